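# eyemorph

Quantitative whole-eye morphometry and shape statistics from 3D binary
eyeball segmentations, for researchers studying how glaucoma and myopia
deform the globe on ocular MRI.

Given a segmented eye mask (NIfTI, typically 0.7 mm isotropic), the package
measures the geometry a clinician would read off multiplanar views:

- **eyeball volume** `V` (mm³): foreground voxels × voxel volume;
- **axial length** `AL` (mm): distance from the corneal apex to the
  posterior retina along the *eye axis* — the normal of the corneal
  tangent plane at the apex;
- **transverse length** `TL` (mm): the widest chord orthogonal to the eye
  axis within the *axial plane* (the tilted plane through apex and optic
  disk spanning the mediolateral direction);
- **anisotropy ratio** `AR = AL / TL`: 1 for a spherical globe, above 1
  for anteroposterior (myopic-type) elongation.

Around the per-eye measurement it provides the full study pipeline:
group-average 3D eye templates (rigid 6-DOF alignment, voxelwise
averaging, smoothing, thresholding), Spearman correlation structure,
two-factor ANOVA (glaucoma × myopia, type-II SS) with Tukey and Dunnett
post-hoc tables, and bootstrapped logistic ROC curves (200 subject-level
half-splits, one eye per subject, vertical curve averaging, AUC of the
mean curve). A phantom generator supplies digitized ellipsoid eyes with
known ground truth and synthetic cohorts matching published group
distributions (eye counts 30/13/33/51/27), so the entire chain is testable
without clinical data.

## Worked example

Measure a digitized phantom with the myopia-group mean geometry
(25.6 mm anteroposterior, 24.3 mm equatorial diameter), then run the
headline classifier on a synthetic cohort:

```r
library(eyemorph)
library(dplyr)

spec <- eye_phantom_spec(semi_axis_ap = 12.8, semi_axis_ml = 12.15,
                         semi_axis_si = 12.15)
mask <- make_eye_mask(spec)
measure_eye(mask)[, 1:4]
#> # A tibble: 1 × 4
#>   volume axial_length transverse_length anisotropy
#>    <dbl>        <dbl>             <dbl>      <dbl>
#> 1  7911.         25.8              24.5       1.05

cohort <- sample_cohort(seed = 7)   # 154 eyes, five groups
count(cohort, group)
#> # A tibble: 5 × 2
#>   group               n
#>   <chr>           <int>
#> 1 control            30
#> 2 glaucoma           33
#> 3 glaucoma_myopia    51
#> 4 myopia             13
#> 5 ppg                27

roc <- cohort |>
  filter(group != "ppg") |>
  mutate(glaucoma = group %in% c("glaucoma", "glaucoma_myopia")) |>
  bootstrap_roc(c("volume", "etiv"), "glaucoma", n_splits = 200, seed = 7)
roc
#> <roc_summary> glaucoma ~ volume + etiv
#>   AUC of mean curve: 0.802 (200 splits)

two_factor_anova(cohort, "anisotropy")
#> <eye_anova> outcome: anisotropy (n = 127 eyes)
#>             term statistic   p_value
#>         glaucoma 1.7422832 0.1893011
#>           myopia 5.8704854 0.0168539
#>  glaucoma:myopia 0.9825083 0.3235263
```

The phantom reads back its ground truth within a voxel (25.8 vs 25.6 mm
axial; 24.5 vs 24.3 mm transverse; anisotropy 1.05 ≈ 25.6/24.3). On this
cohort draw, eye volume normalized by intracranial volume discriminates
glaucomatous from non-glaucomatous eyes with a mean-curve AUC of 0.80, and
myopia — but not glaucoma — raises the anisotropy ratio, the elongation
signature the measurement is designed to capture.

`run_pipeline(pipeline_config(seed = 1))` executes the five stages
(simulate → measure → template → stats → roc) end to end, writing CSV/JSON
outputs, NIfTI templates and a hash manifest; `report_run()` renders the
group table, correlation heatmap, group bars and ROC figure. A thin CLI
over the same functions is installed at `inst/cli/eyemorph.R`.

Fitted-object methods follow broom conventions: `tidy()`, `glance()` and
`autoplot()` work on correlation matrices, ANOVA results and ROC
summaries.

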