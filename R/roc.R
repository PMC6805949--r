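# Bootstrapped logistic-regression ROC analysis. Each of the random splits
# keeps one eye per subject (eyes of one subject are strongly correlated and
# would otherwise leak between the fit and evaluation halves), fits a
# logistic model on a random half of the subjects, and evaluates the ROC on
# the held-out half; the displayed curve is the vertical (fixed-FPR) average
# of the per-split curves and the AUC is computed on that average curve.

# Empirical TPR at each grid FPR for scores/labels of one evaluation half.
# The per-split curve is linearly interpolated between its ROC vertices
# (max TPR per attained FPR), the standard construction for vertical
# (fixed-FPR) curve averaging; with the small evaluation halves a step
# interpolation would bias the averaged curve pessimistically by up to half
# a step between attained FPR values.
tpr_at_fpr <- function(scores, labels, fpr_grid) {
  pos <- scores[labels]
  neg <- scores[!labels]
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)))
  tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  best <- vapply(unique(fpr), function(f) max(tpr[fpr == f]), numeric(1))
  stats::approx(unique(fpr), best, xout = fpr_grid, rule = 2)$y
}

fit_logistic <- function(x, y) {
  # returns a linear scoring function; falls back to a small ridge penalty
  # when the ML fit separates or fails to converge
  ridge_used <- FALSE
  fit <- tryCatch(
    suppressWarnings(glm(y ~ ., data = data.frame(x, y = y),
                         family = binomial())),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$converged &&
    all(is.finite(coef(fit))) && max(abs(coef(fit)[-1]), na.rm = TRUE) < 50
  if (ok) {
    beta <- coef(fit)
  } else {
    ridge_used <- TRUE
    xm <- as.matrix(x)
    if (ncol(xm) == 1) xm <- cbind(xm, 0)  # glmnet needs >= 2 columns
    rf <- suppressWarnings(  # small-n warnings; the event is counted upstream
      glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                     lambda = 1e-4, standardize = FALSE))
    beta <- c(as.numeric(rf$a0), as.numeric(rf$beta)[seq_len(ncol(x))])
  }
  list(beta = beta, ridge_used = ridge_used)
}

#' Bootstrapped logistic ROC summary
#'
#' Generates `n_splits` random half-splits of the subjects. In each split
#' one eye per subject is kept (chosen at random), subjects are divided
#' 50/50 into a fit half and an evaluation half, a logistic regression on
#' the standardized predictors is fitted by maximum likelihood on the fit
#' half (with a small ridge penalty as fallback on separation; occurrences
#' are counted in `n_ridge`), and the evaluation half's empirical ROC is
#' read off at a fixed FPR grid. The reported curve is the pointwise mean
#' TPR over splits with its SD band, and the AUC is the trapezoidal area
#' under the mean curve.
#'
#' @param table cohort tibble (one row per eye, with `subject_id`).
#' @param predictors character vector of predictor column names.
#' @param label name of a logical column (or one coercible to logical)
#'   marking the positive class.
#' @param n_splits number of random splits.
#' @param seed integer seed.
#' @param fpr_grid grid of false-positive rates.
#' @return an object of class `roc_summary`: `fpr_grid`, `mean_tpr`,
#'   `tpr_sd`, `auc_of_mean_curve`, `n_splits`, `n_ridge`, `predictors`,
#'   `label`.
#' @export
bootstrap_roc <- function(table, predictors, label, n_splits = 200, seed = 1,
                          fpr_grid = seq(0, 1, by = 0.02)) {
  stopifnot(all(predictors %in% names(table)), label %in% names(table),
            "subject_id" %in% names(table))
  y_all <- as.logical(table[[label]])
  if (anyNA(y_all)) stop("label contains missing values")
  n_subj_pos <- length(unique(table$subject_id[y_all]))
  n_subj_neg <- length(unique(table$subject_id[!y_all]))
  if (n_subj_pos < 10 || n_subj_neg < 10)
    stop("need at least 10 subjects per class")
  subjects <- unique(table$subject_id)
  tprs <- matrix(NA_real_, n_splits, length(fpr_grid))
  n_ridge <- 0L
  set.seed(seed)
  for (s in seq_len(n_splits)) {
    repeat {
      # one eye per subject, selected at random
      idx <- vapply(split(seq_len(nrow(table)), table$subject_id),
                    function(i) if (length(i) == 1) i else sample(i, 1),
                    integer(1))
      dat <- table[idx, ]
      half <- sample(subjects, floor(length(subjects) / 2))
      fit_rows <- dat$subject_id %in% half
      y_fit <- as.logical(dat[[label]][fit_rows])
      y_ev <- as.logical(dat[[label]][!fit_rows])
      if (length(unique(y_fit)) == 2 && length(unique(y_ev)) == 2) break
    }
    x <- as.data.frame(dat[, predictors])
    mu <- vapply(x[fit_rows, , drop = FALSE], mean, numeric(1))
    sdv <- vapply(x[fit_rows, , drop = FALSE], sd, numeric(1))
    sdv[sdv == 0] <- 1
    xs <- as.data.frame(scale(x, center = mu, scale = sdv))
    fit <- fit_logistic(xs[fit_rows, , drop = FALSE], y_fit)
    if (fit$ridge_used) n_ridge <- n_ridge + 1L
    scores <- as.matrix(cbind(1, xs[!fit_rows, , drop = FALSE])) %*% fit$beta
    tprs[s, ] <- tpr_at_fpr(as.numeric(scores), y_ev, fpr_grid)
  }
  mean_tpr <- colMeans(tprs)
  auc <- sum(diff(fpr_grid) * (head(mean_tpr, -1) + tail(mean_tpr, -1)) / 2)
  structure(list(fpr_grid = fpr_grid, mean_tpr = mean_tpr,
                 tpr_sd = apply(tprs, 2, sd),
                 auc_of_mean_curve = auc, n_splits = n_splits,
                 n_ridge = n_ridge, predictors = predictors, label = label),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> %s ~ %s\n", x$label,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  AUC of mean curve: %.3f (%d splits%s)\n",
              x$auc_of_mean_curve, x$n_splits,
              if (x$n_ridge > 0) sprintf(", %d ridge fallbacks", x$n_ridge)
              else ""))
  invisible(x)
}

#' @export
tidy.roc_summary <- function(x, ...) {
  tibble::tibble(fpr = x$fpr_grid, mean_tpr = x$mean_tpr, tpr_sd = x$tpr_sd)
}

#' @export
glance.roc_summary <- function(x, ...) {
  tibble::tibble(auc = x$auc_of_mean_curve, n_splits = x$n_splits,
                 n_ridge = x$n_ridge,
                 predictors = paste(x$predictors, collapse = "+"))
}

#' @export
autoplot.roc_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$mean_tpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean_tpr - .data$tpr_sd / 2),
                                      ymax = pmin(1, .data$mean_tpr + .data$tpr_sd / 2)),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("%s ~ %s (AUC = %.2f)", object$label,
                      paste(object$predictors, collapse = " + "),
                      object$auc_of_mean_curve)) +
    ggplot2::theme_minimal()
}

#' Compare candidate predictor sets by bootstrapped AUC
#'
#' Runs [bootstrap_roc()] for each predictor set under a common seed (so
#' splits are identical across models) and ranks the models by AUC of the
#' mean curve, reporting the FPR at 80% sensitivity as an operating point.
#'
#' @param table cohort tibble.
#' @param model_specs named list of character vectors of predictors.
#' @param label positive-class column name.
#' @param ... passed to [bootstrap_roc()].
#' @return a tibble sorted by decreasing AUC, with the full `roc_summary`
#'   objects in a list-column `roc`.
#' @export
model_comparison <- function(table, model_specs, label, ...) {
  stopifnot(length(model_specs) > 0)
  if (is.null(names(model_specs)))
    names(model_specs) <- vapply(model_specs, paste, character(1),
                                 collapse = "+")
  rocs <- purrr::map(model_specs, function(p)
    bootstrap_roc(table, p, label, ...))
  tbl <- tibble::tibble(
    model = names(model_specs),
    predictors = vapply(model_specs, paste, character(1), collapse = "+"),
    auc = vapply(rocs, function(r) r$auc_of_mean_curve, numeric(1)),
    fpr_at_80_sens = vapply(rocs, function(r) {
      i <- which(r$mean_tpr >= 0.8)
      if (length(i) == 0) NA_real_ else r$fpr_grid[min(i)]
    }, numeric(1)),
    roc = unname(rocs))
  dplyr::arrange(tbl, dplyr::desc(.data$auc))
}
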