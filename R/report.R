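# Summary reporting from a completed run directory.

#' Group summary table
#'
#' Mean and SD of the morphometric and demographic variables per group, in
#' the layout of a clinical characteristics table.
#'
#' @param table cohort (or joined cohort + morphometry) tibble.
#' @param variables variables to summarize.
#' @return a tibble with one row per variable and `mean (SD)` strings per
#'   group.
#' @export
group_summary_table <- function(table,
                                variables = c("iop", "age", "height", "etiv",
                                              "se", "md", "volume", "axial",
                                              "transverse", "anisotropy")) {
  variables <- intersect(variables, names(table))
  long <- tidyr::pivot_longer(
    dplyr::select(table, "group", dplyr::all_of(variables)),
    -"group", names_to = "variable", values_to = "value")
  wide <- dplyr::summarise(
    dplyr::group_by(long, .data$variable, .data$group),
    cell = sprintf("%.1f ± %.1f", mean(.data$value, na.rm = TRUE),
                   sd(.data$value, na.rm = TRUE)), .groups = "drop")
  out <- tidyr::pivot_wider(wide, names_from = "group", values_from = "cell")
  out[match(variables, out$variable), ]
}

#' Group mean/SD bar plot for one outcome
#'
#' @param table cohort tibble.
#' @param outcome outcome column name (string).
#' @return a ggplot.
#' @export
plot_group_means <- function(table, outcome) {
  stopifnot(outcome %in% names(table))
  df <- dplyr::summarise(dplyr::group_by(table, .data$group),
                         m = mean(.data[[outcome]], na.rm = TRUE),
                         s = sd(.data[[outcome]], na.rm = TRUE),
                         .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$m)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$s,
                                        ymax = .data$m + .data$s),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$rho, rownames = "var1"),
    -"var1", names_to = "var2", values_to = "rho")
  df$var1 <- factor(df$var1, levels = object$variables)
  df$var2 <- factor(df$var2, levels = rev(object$variables))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render a summary report from a run directory
#'
#' Rebuilds the headline artifacts of a completed [run_pipeline()] run: the
#' group characteristics table, the correlation heatmap, group mean bar
#' plots and the glaucoma ROC curve. Figures are saved as PNG under
#' `<out_dir>/report/`. Missing stage outputs are listed in the result
#' rather than raising an error.
#'
#' @param manifest an `eyemorph_manifest` (or a run directory path).
#' @return a list: `group_table`, `figures` (paths), `missing`.
#' @export
report_run <- function(manifest) {
  out_dir <- if (is.character(manifest)) manifest else manifest$out_dir
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- character(0)
  figures <- character(0)
  group_table <- NULL

  cohort_path <- file.path(out_dir, "cohort.csv")
  morpho_path <- file.path(out_dir, "morphometry.csv")
  if (file.exists(cohort_path)) {
    cohort <- read_cohort(cohort_path)
    if (file.exists(morpho_path)) {
      m <- read_cohort(morpho_path)
      cohort <- dplyr::left_join(
        dplyr::select(cohort, -dplyr::any_of(c("volume", "axial",
                                               "transverse", "anisotropy"))),
        dplyr::select(m, "subject_id", "eye_side", volume = "volume",
                      axial = "axial_length", transverse = "transverse_length",
                      anisotropy = "anisotropy"),
        by = c("subject_id", "eye_side"))
    }
    group_table <- group_summary_table(cohort)
    corr <- spearman_matrix(cohort)
    p <- autoplot(corr)
    f <- file.path(rep_dir, "correlations.png")
    ggplot2::ggsave(f, p, width = 6, height = 5, dpi = 120)
    figures <- c(figures, f)
    for (o in intersect(c("volume", "anisotropy"), names(cohort))) {
      p <- plot_group_means(cohort, o)
      f <- file.path(rep_dir, paste0("group_", o, ".png"))
      ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
      figures <- c(figures, f)
    }
  } else {
    missing <- c(missing, "cohort.csv")
  }

  roc_path <- file.path(out_dir, "roc_glaucoma.csv")
  if (file.exists(roc_path)) {
    rc <- read_cohort(roc_path)
    p <- ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$mean_tpr)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean_tpr - .data$tpr_sd / 2),
                                        ymax = pmin(1, .data$mean_tpr + .data$tpr_sd / 2)),
                           fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
      ggplot2::theme_minimal()
    f <- file.path(rep_dir, "roc_glaucoma.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
    figures <- c(figures, f)
  } else {
    missing <- c(missing, "roc_glaucoma.csv")
  }
  list(group_table = group_table, figures = figures, missing = missing)
}
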