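---
title: "Whole-eye morphometry from 3D segmentations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-eye morphometry from 3D segmentations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyemorph)
```

## The problem

Glaucomatous and myopic deformation change the three-dimensional shape of
the eyeball in different ways: myopic eyes elongate anteroposteriorly into
a prolate ellipsoid, while glaucomatous enlargement tends to stay
near-spherical, sometimes with a localized infero-nasal protrusion of the
posterior globe. High-resolution MRI segmentations of whole eyes make these
differences measurable. `eyemorph` implements the full quantitative chain:
it measures eyeball **volume**, **axial length**, **transverse length** and
their ratio (the **anisotropy ratio**) from a binary 3D mask, builds
group-average 3D eye shapes by rigid alignment and voxelwise averaging, and
runs the cohort statistics used to relate these measurements to disease
status — Spearman correlation structure, a glaucoma-by-myopia two-factor
ANOVA with Tukey and Dunnett post-hoc tables, and bootstrapped
logistic-regression ROC analysis.

Because clinical imaging data cannot be redistributed, the package ships a
first-class phantom generator: digitized eye masks with known ground-truth
geometry and synthetic cohorts whose per-group distributions follow the
published group summary table (eye counts 30/13/33/51/27 for control,
myopia, glaucoma, glaucoma-with-myopia, and preperimetric glaucoma). Every
downstream stage is tested against these known truths.

## The measurement model

A mask is a binary voxel grid (default 0.7 mm isotropic, the reconstructed
resolution of the source acquisitions) with +x = right, +y = anterior,
+z = superior. The measurement frame follows the clinical construction:

- **Surface.** The level-0.5 isosurface of the binary grid, represented as
  the midpoints of foreground/background voxel faces. For binary data these
  are exactly the points where trilinear interpolation crosses 0.5 along
  grid axes, giving subvoxel localization without triangulation.
- **Corneal apex.** An anatomical landmark when available (phantom ground
  truth or a sidecar annotation); otherwise the anterior-most surface point,
  ties resolved by their centroid. The fallback is adequate for eyes imaged
  in near-anterior gaze; at large rotations the anterior extremum is a
  support point whose tangent plane is always horizontal, so annotated
  landmarks are preferred whenever they exist.
- **Eye axis.** Normal of the corneal tangent plane, fitted by total least
  squares to surface points within 4 mm of the apex and oriented towards
  the mask centroid. A 3 mm cap holds only ~75 surface points at 0.7 mm
  sampling and lets digitization noise tilt the normal by up to ~2 degrees;
  4 mm keeps the error below ~0.7 degrees while staying on the cornea.
- **Optic disk.** Landmark passthrough when supplied; otherwise the
  posterior pole (surface point farthest from the apex). A binary mask
  contains no disk anatomy, so the fallback is an explicit approximation.
- **Axial plane.** The plane through apex and disk whose normal is
  orthogonal to the left-right axis — the tilted transverse-anatomical
  plane spanning the apex-disk line and the mediolateral direction. A plane
  through two points is otherwise underdetermined; this third constraint
  reproduces the tilted axial plane used clinically.
- **Axial length.** Distance from the apex to the *last* intersection of
  the posterior ray along the eye axis with the isosurface (ray marching at
  a tenth of a voxel with linear refinement). Taking the last crossing is
  robust to local concavities next to posterior protrusions.
- **Transverse length.** The maximum chord orthogonal to the eye axis,
  confined to the axial plane, over stations along the axis. A
  `transverse_3d` flag instead maximizes over all orthogonal directions;
  the in-plane default matches how the measurement is drawn clinically.
- **Volume.** Foreground voxel count times voxel volume — deliberately the
  granularity of threshold-contour segmentation tools, while lengths use
  the subvoxel surface.
- **Anisotropy ratio** = axial / transverse, exactly; 1 is spherical,
  above 1 anteroposteriorly elongated.

Digitization accuracy at 0.7 mm voxels: lengths recover ellipsoid ground
truth within one voxel and volumes within 2% of \(\tfrac{4}{3}\pi abc\)
across orientations (these bounds are asserted by the test suite).

## The phantom generator

`eye_phantom_spec()` describes an ellipsoid (semi-axes in mm) with an
optional localized protrusion: a radial offset
\(A\,e^{-\theta^2/2w^2}\) about a bump direction, with amplitude default
0.8 mm and angular width 40 degrees — a deliberately simple stand-in for
the qualitative infero-nasal protrusion reported in glaucomatous eyes,
since only its direction and rough size are published. `make_eye_mask()`
rasterizes by voxel-center inclusion (no partial volume), matching
threshold-contour segmentation granularity.

`sample_cohort()` draws per-eye records from a Gaussian copula with
Gaussian marginals. Spearman targets are converted to latent Pearson
correlations via \(2\sin(\pi\rho/6)\) (only rank correlations are
published). Subjects contribute two eyes: age, height, eTIV and sex are
shared exactly within subject; eye-level variables use a common-factor
construction giving a latent between-eye correlation of 0.8, a realistic
figure for ocular biometry chosen once (the published data report no
inter-eye correlation). Records violating the exclusion rules (spherical
equivalent of −8 D or worse, or non-physical non-positive values) are
redrawn rather than clipped, preserving the marginal shape elsewhere.
Per-subject random streams derive from the master seed by counter offset,
so any subset of groups reproduces its records.

Within-group correlation defaults (see `default_correlation_spec()`):
volume couples strongly (0.75) to the two diameters, moderately (0.40) to
the body-size normalizers height and eTIV — the published pooled values —
and axial elongation tracks myopic refraction negatively (−0.45).
Visual-field and pressure variables are left uncorrelated within group;
their pooled associations arise from group mean differences. Sampled SE can
straddle the −3 D myopia boundary because the group marginals take
priority over label consistency; `assign_groups()` is provided for
workflows that derive labels from measurements instead.

Two deliberate stand-ins, chosen once and documented here: the ordinal
"glaucoma stage" is binned from the visual-field mean deviation
Hodapp-style (stage 1/2/3/4 at MD ≥ −6, [−12, −6), [−20, −12), < −20 dB),
since the clinical staging behind the published figure is not defined; and
the preperimetric group is sampled from a single Gaussian per variable
although it pools myopic and non-myopic eyes. One printed value was
corrected as a typo: the preperimetric transverse-length SD of 11.3 mm
(an order of magnitude out of line with every other group and with the
printed anisotropy SD); the generator uses 1.3 mm.

What the phantoms do *not* emulate: MR intensities, partial-volume
effects, motion, segmentation-rater variability, corneal/lens substructure,
or realistic per-eye shape irregularity beyond the single bump. Passing
tests therefore demonstrate correctness of the measurement and statistics
chain on idealized geometry, not robustness to real segmentation noise.

## Template averaging

Group-average eye shapes follow a two-pass aligned-averaging scheme:

1. a *blurry initial template* — the voxelwise average after translating
   each mask's centroid to a common grid center;
2. rigid (6-DOF, no scaling — size differences are signal) alignment of
   every mask to it, and re-averaging into a sharper global template;
3. within-group alignment to that template and averaging;
4. Gaussian smoothing (default σ = one voxel) and thresholding at 0.5.

Left and right eyes are processed independently; no mirroring.

The registration metric is the mean template probability over the
transformed foreground sample points (for binary masks, equivalent to
overlap up to normalization). Two numerical details matter and are easy to
get wrong: the template is blurred (σ = 1 voxel) for scoring, because a
hard binary template plateaus the objective; and the sample points are
jittered uniformly within their voxel (fixed per call, so the objective is
deterministic), because masks digitized on the same grid as the template
otherwise lock onto the spurious grid-coincident optimum. Optimization is
Nelder-Mead with one restart from two starts: centroid-matched identity and
a principal-axes rotation with sign-matched eigenvectors (rejected when it
implies an implausible flip, as principal axes of near-spherical blobs
are unstable). If refinement cannot improve on its initialization, the
initialization is returned with a warning flag.

## Cohort statistics

- **Correlations.** Pairwise-complete Spearman with average-rank ties and
  asymptotic t p-values; `stratified_correlations()` applies a filter
  first (e.g. excluding the preperimetric group).
- **ANOVA.** Glaucoma and myopia crossed over the four 2×2 groups
  (preperimetric excluded), type-II sums of squares because the printed
  group sizes (30/13/33/51) are unbalanced. Tukey HSD covers the six group
  pairs; Dunnett compares each group against control — the two post-hoc
  procedures are kept side by side because the source analyses used each in
  different places. Eyes are treated as observations, as in the source
  analyses; with two correlated eyes per subject the p-values are
  anti-conservative, which is one reason the classifier stage resamples
  one eye per subject.
- **ROC.** For each of `n_splits` (default 200) splits: one eye per
  subject at random; subjects halved at random (resampled if a half lacks
  a class); logistic regression by maximum likelihood on fit-half
  standardized predictors (a ridge penalty of 1e-4 substitutes only on
  separation or non-convergence, and such events are counted); the
  evaluation half's empirical ROC is read at a fixed FPR grid by linear
  interpolation between attained ROC vertices — the standard vertical
  averaging construction. The displayed band is ±half the pointwise SD and
  the AUC is the trapezoidal area under the *mean* curve. At the study's
  sample sizes an evaluation half holds only ~11 negative subjects;
  vertex interpolation then sits a few hundredths above the Mann-Whitney
  staircase, which is why null-calibration checks average over many
  permutations rather than trusting a single one.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at the scale the
package documents: phantoms at 0.7 mm voxels (grids of roughly 45³),
cohorts at the published group sizes (154 eyes), 200 ROC splits, and
small mask sets (4–8) for template identity checks; ANOVA calibration uses
1000 permutation replicates. A full five-stage pipeline run on the default
configuration, including all per-group templates, takes minutes of CPU and
is driven by `run_pipeline()`; every random draw derives from the single
config seed, and the manifest records file hashes so reruns can be
compared. Headline quantities have cohort-draw variability (the classifier
AUC varies by ~0.05 SD across cohort seeds at n = 127), so expectation
estimates average over replicate cohorts.

## Known limitations

- The optic-disk fallback (posterior pole) is a geometric approximation;
  on real data the disk should be annotated from anatomy and passed as a
  landmark.
- Rigid alignment assumes blob-like shapes; it is not a general-purpose
  registration and offers no nonrigid mode, statistical shape model, or
  surface rendering beyond a PLY point-cloud export.
- The copula cohort reproduces first and second moments and rank
  correlations, not higher-order structure of clinical populations; group
  labels are sampled, not diagnosed.
- Volume is voxel-count based; at 0.7 mm this is accurate to ~1–2% for
  eye-sized objects but inherits the segmentation's partial-volume
  convention.
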