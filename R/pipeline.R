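# End-to-end orchestration: simulate -> measure -> template -> stats -> roc,
# with every random draw traceable to the master seed and a JSON manifest of
# what was produced.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one serializable list.
#' Defaults reproduce the standard study conditions: the five-group cohort
#' of [default_group_params()], 0.7 mm voxels, one-voxel template smoothing
#' with a 0.5 threshold, and 200 ROC splits.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param voxel_size isotropic voxel edge, mm.
#' @param group_params see [default_group_params()].
#' @param correlation_spec see [default_correlation_spec()].
#' @param eyes_per_subject,rho_between_eyes see [sample_cohort()].
#' @param template_sigma smoothing SD in mm (`NULL` = one voxel).
#' @param template_threshold probability threshold of the final mask.
#' @param template_rounds global align-average refinement rounds.
#' @param template_groups groups to build templates for (`NULL` = the four
#'   2x2 study groups).
#' @param roc_n_splits bootstrap splits per ROC model.
#' @param roc_fpr_grid FPR grid for curve averaging.
#' @param write_masks also write every phantom mask as NIfTI.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, voxel_size = 0.7,
                            group_params = default_group_params(),
                            correlation_spec = default_correlation_spec(),
                            eyes_per_subject = 2, rho_between_eyes = 0.8,
                            template_sigma = NULL, template_threshold = 0.5,
                            template_rounds = 1, template_groups = NULL,
                            roc_n_splits = 200,
                            roc_fpr_grid = seq(0, 1, by = 0.02),
                            write_masks = FALSE,
                            out_dir = tempfile("eyemorph_run_")) {
  structure(list(seed = seed, voxel_size = voxel_size,
                 group_params = group_params,
                 correlation_spec = correlation_spec,
                 eyes_per_subject = eyes_per_subject,
                 rho_between_eyes = rho_between_eyes,
                 template_sigma = template_sigma,
                 template_threshold = template_threshold,
                 template_rounds = template_rounds,
                 template_groups = template_groups,
                 roc_n_splits = roc_n_splits, roc_fpr_grid = roc_fpr_grid,
                 write_masks = write_masks, out_dir = out_dir),
            class = "pipeline_config")
}

stage_error <- function(stage, e) {
  stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

# Build templates for several groups sharing the global alignment pass.
build_templates_shared <- function(masks, groups, wanted, sigma, threshold,
                                   rounds) {
  global <- voxelwise_average(masks)
  for (r in seq_len(rounds)) {
    global <- new_eye_template(aligned_average(masks, global)$prob,
                               masks[[1]]$voxel_size,
                               n_contributing = length(masks))
  }
  out <- list()
  for (g in wanted) {
    in_group <- which(groups == g)
    if (length(in_group) < 2) next
    grp <- aligned_average(masks[in_group], global)
    vs <- masks[[1]]$voxel_size
    smoothed <- gaussian_smooth_3d(grp$prob, sigma / vs)
    side <- unique(stats::na.omit(sapply(masks[in_group],
                                         function(m) m$eye_side)))
    out[[g]] <- new_eye_template(
      grp$prob, vs, n_contributing = length(in_group), group_label = g,
      eye_side = if (length(side) == 1) side else NA_character_,
      final_mask = smoothed >= threshold)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on one configuration: `simulate`
#' (synthetic cohort and phantom masks), `measure` (per-eye morphometry),
#' `template` (per-group, per-side average eye shapes), `stats` (Spearman
#' matrix, stratified correlations, two-factor ANOVAs) and `roc`
#' (bootstrapped logistic models for glaucoma and myopia discrimination).
#' Outputs are written under `config$out_dir`; a failure aborts with a
#' stage-tagged error, retaining the outputs of completed stages.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (prerequisites are run implicitly).
#' @return the run manifest (also written as `manifest.json`): seed,
#'   package version, per-stage outputs, counts and file MD5 hashes.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "measure", "template",
                                    "stats", "roc")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("eyemorph")),
                   seed = config$seed, stages = stages, files = list())
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }

  if (any(config$group_params$n_eyes <= 0))
    stage_error("simulate", simpleError("no masks: every group needs n_eyes > 0"))

  cohort <- tryCatch(
    sample_cohort(config$group_params, config$correlation_spec,
                  seed = config$seed,
                  eyes_per_subject = config$eyes_per_subject,
                  rho_between_eyes = config$rho_between_eyes),
    error = function(e) stage_error("simulate", e))
  masks <- tryCatch(
    masks_from_cohort(cohort, seed = derive_seed(config$seed, 1),
                      voxel_size = config$voxel_size),
    error = function(e) stage_error("simulate", e))
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  add_file(cohort_path)
  if (isTRUE(config$write_masks)) {
    mask_dir <- file.path(config$out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (nm in names(masks))
      write_eye_mask(masks[[nm]], file.path(mask_dir, paste0(nm, ".nii.gz")))
  }
  manifest$n_eyes <- nrow(cohort)
  manifest$n_masks <- length(masks)

  measured <- NULL
  if (any(c("measure", "stats", "roc") %in% stages)) {
    measured <- tryCatch(measure_cohort(masks),
                         error = function(e) stage_error("measure", e))
    measured$subject_id <- sub("_(left|right)$", "", measured$mask_id)
    measured$eye_side <- sub("^.*_(left|right)$", "\\1", measured$mask_id)
    morpho_path <- file.path(config$out_dir, "morphometry.csv")
    write.csv(as.data.frame(measured), morpho_path, row.names = FALSE)
    add_file(morpho_path)
    manifest$n_measured <- nrow(measured)
  }

  if ("template" %in% stages) {
    wanted <- config$template_groups %||%
      c("control", "myopia", "glaucoma", "glaucoma_myopia")
    sigma <- config$template_sigma %||% config$voxel_size
    tryCatch({
      for (side in c("left", "right")) {
        sel <- which(cohort$eye_side == side)
        if (length(sel) < 2) next
        tmpls <- build_templates_shared(
          masks[sel], cohort$group[sel], wanted, sigma,
          config$template_threshold, config$template_rounds)
        for (g in names(tmpls)) {
          base <- file.path(config$out_dir,
                            sprintf("template_%s_%s", g, side))
          tm <- tmpls[[g]]
          img <- RNifti::asNifti(tm$probability_volume)
          RNifti::pixdim(img) <- tm$voxel_size
          RNifti::writeNifti(img, paste0(base, "_prob.nii.gz"))
          write_eye_mask(template_to_mask(tm), paste0(base, "_mask.nii.gz"))
          add_file(paste0(base, "_prob.nii.gz"))
          add_file(paste0(base, "_mask.nii.gz"))
        }
      }
    }, error = function(e) stage_error("template", e))
  }

  joined <- NULL
  if (any(c("stats", "roc") %in% stages)) {
    joined <- dplyr::left_join(
      dplyr::select(cohort, -dplyr::any_of(c("volume", "axial", "transverse",
                                             "anisotropy"))),
      dplyr::select(measured, dplyr::all_of(c("subject_id", "eye_side")),
                    volume = "volume", axial = "axial_length",
                    transverse = "transverse_length",
                    anisotropy = "anisotropy"),
      by = c("subject_id", "eye_side"))
  }

  if ("stats" %in% stages) {
    tryCatch({
      corr <- spearman_matrix(joined)
      write.csv(as.data.frame(corr$rho),
                file.path(config$out_dir, "correlations.csv"))
      add_file(file.path(config$out_dir, "correlations.csv"))
      strat <- stratified_correlations(joined, .data$group != "ppg")
      anovas <- lapply(c("volume", "anisotropy"), function(o)
        two_factor_anova(joined, o))
      names(anovas) <- c("volume", "anisotropy")
      report <- list(
        stratified_stage_volume_rho = strat$rho["stage", "volume"],
        anova = lapply(anovas, function(a)
          list(effects = as.data.frame(a$effects),
               tukey = as.data.frame(a$tukey),
               dunnett = as.data.frame(a$dunnett))))
      jsonlite::write_json(report, file.path(config$out_dir, "anova.json"),
                           auto_unbox = TRUE, digits = NA)
      add_file(file.path(config$out_dir, "anova.json"))
    }, error = function(e) stage_error("stats", e))
  }

  if ("roc" %in% stages) {
    tryCatch({
      roc_tab <- dplyr::filter(joined, .data$group != "ppg")
      roc_tab$glaucoma <- roc_tab$group %in% c("glaucoma", "glaucoma_myopia")
      roc_tab$myopia_label <- roc_tab$group %in% c("myopia", "glaucoma_myopia")
      glauc <- bootstrap_roc(roc_tab, c("volume", "etiv"), "glaucoma",
                             n_splits = config$roc_n_splits,
                             seed = derive_seed(config$seed, 2),
                             fpr_grid = config$roc_fpr_grid)
      myop <- model_comparison(
        roc_tab,
        list(axial_transverse = c("axial", "transverse"),
             volume = "volume",
             axial_height = c("axial", "height")),
        "myopia_label", n_splits = config$roc_n_splits,
        seed = derive_seed(config$seed, 3),
        fpr_grid = config$roc_fpr_grid)
      write.csv(as.data.frame(tidy(glauc)),
                file.path(config$out_dir, "roc_glaucoma.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(glaucoma = list(predictors = glauc$predictors,
                             auc = glauc$auc_of_mean_curve,
                             n_splits = glauc$n_splits),
             myopia_models = as.data.frame(
               dplyr::select(myop, -"roc"))),
        file.path(config$out_dir, "roc.json"), auto_unbox = TRUE, digits = NA)
      add_file(file.path(config$out_dir, "roc_glaucoma.csv"))
      add_file(file.path(config$out_dir, "roc.json"))
    }, error = function(e) stage_error("roc", e))
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  structure(c(manifest, list(out_dir = config$out_dir)),
            class = "eyemorph_manifest")
}

#' @export
print.eyemorph_manifest <- function(x, ...) {
  cat("<eyemorph run>\n")
  cat("  seed:", x$seed, "\n")
  cat("  eyes:", x$n_eyes, "| measured:", x$n_measured %||% 0, "\n")
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
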