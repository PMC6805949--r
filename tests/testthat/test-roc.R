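test_that("a perfectly separating predictor reaches AUC 1", {
  tab <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:40),
    score = c(rnorm(20, 10, 0.5), rnorm(20, 0, 0.5)),
    disease = rep(c(TRUE, FALSE), each = 20))
  r <- bootstrap_roc(tab, "score", "disease", n_splits = 50, seed = 1)
  expect_equal(r$auc_of_mean_curve, 1, tolerance = 1e-9)
  expect_true(all(diff(r$mean_tpr) >= -1e-12))  # monotone mean curve
})

test_that("permuted labels give chance-level AUC", {
  # a single fixed permutation keeps its chance association in both split
  # halves (null SD of AUC ~ 0.05 at the study n), so calibration is
  # averaged over permutations, on a larger cohort where the
  # vertex-interpolation offset of the tiny evaluation halves is small
  coh <- with_glaucoma_label(small_cohort(seed = 29, scale = 3))
  set.seed(5)
  aucs <- vapply(1:6, function(i) {
    coh$perm <- sample(coh$glaucoma)
    bootstrap_roc(coh, c("volume", "etiv"), "perm", n_splits = 50,
                  seed = i)$auc_of_mean_curve
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUC is invariant under monotone transforms of a single predictor", {
  coh <- with_glaucoma_label(sample_cohort(seed = 31))
  r1 <- bootstrap_roc(coh, "volume", "glaucoma", n_splits = 50, seed = 3)
  coh$volume_t <- exp(coh$volume / 2000)
  r2 <- bootstrap_roc(coh, "volume_t", "glaucoma", n_splits = 50, seed = 3)
  expect_equal(r1$mean_tpr, r2$mean_tpr, tolerance = 1e-9)
  expect_equal(r1$auc_of_mean_curve, r2$auc_of_mean_curve, tolerance = 1e-9)
})

test_that("the averaged curve matches an independent ROC computation per split", {
  skip_if_not_installed("pROC")
  # one degenerate-free split, no subject resampling: our empirical curve
  # must agree with pROC on the same scores
  set.seed(7)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  grid <- seq(0, 1, by = 0.01)
  ours <- eyemorph:::tpr_at_fpr(scores, labels, grid)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  auc_ours <- sum(diff(grid) * (head(ours, -1) + tail(ours, -1)) / 2)
  # vertex-linear interpolation sits slightly above the Mann-Whitney
  # staircase (about half a cell per step: ~1/(2*30) here)
  expect_equal(auc_ours, as.numeric(pROC::auc(pr)), tolerance = 0.02)
})

test_that("class-size and label preconditions are enforced", {
  tab <- tibble::tibble(subject_id = sprintf("s%d", 1:12),
                        x = rnorm(12), y = rep(c(TRUE, FALSE), c(3, 9)))
  expect_error(bootstrap_roc(tab, "x", "y"), "at least 10 subjects")
})

test_that("ROC summary accessors expose the curve and the fit count", {
  coh <- with_glaucoma_label(sample_cohort(seed = 37))
  r <- bootstrap_roc(coh, c("volume", "etiv"), "glaucoma",
                     n_splits = 40, seed = 11)
  td <- tidy(r)
  expect_named(td, c("fpr", "mean_tpr", "tpr_sd"))
  expect_equal(nrow(td), length(r$fpr_grid))
  g <- glance(r)
  expect_equal(g$auc, r$auc_of_mean_curve)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})

test_that("model comparison ranks with a common seed and guards overfit", {
  coh <- with_glaucoma_label(sample_cohort(seed = 41))
  set.seed(8)
  coh$noise <- rnorm(nrow(coh))
  cmp <- model_comparison(
    coh,
    list(volume = "volume", volume_again = "volume",
         volume_noise = c("volume", "noise")),
    "glaucoma", n_splits = 60, seed = 13)
  aucs <- setNames(cmp$auc, cmp$model)
  expect_equal(unname(aucs["volume"]), unname(aucs["volume_again"]))
  expect_lt(aucs["volume_noise"] - aucs["volume"], 0.03)
  expect_true(all(diff(cmp$auc) <= 1e-12))  # sorted decreasing
})

test_that("axial plus transverse tends to beat volume alone for myopia", {
  # ordering check at cohort scale: the shape model should win on most
  # cohort draws, not necessarily on every one
  wins <- vapply(1:5, function(s) {
    coh <- with_glaucoma_label(sample_cohort(seed = s))
    cmp <- model_comparison(
      coh, list(axial_transverse = c("axial", "transverse"),
                volume = "volume"),
      "myopia_label", n_splits = 80, seed = s)
    cmp$model[1] == "axial_transverse"
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("bootstrap AUC dispersion shrinks with the number of splits", {
  coh <- with_glaucoma_label(sample_cohort(seed = 47))
  sd_at <- function(n_splits) {
    sd(vapply(1:6, function(i)
      bootstrap_roc(coh, c("volume", "etiv"), "glaucoma",
                    n_splits = n_splits, seed = 100 + i)$auc_of_mean_curve,
      numeric(1)))
  }
  expect_gt(sd_at(25), sd_at(400))
})
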