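test_that("default cohort reproduces the study group sizes", {
  gp <- default_group_params()
  expect_equal(gp$n_eyes, c(30L, 13L, 33L, 51L, 27L))
  expect_equal(sum(gp$n_eyes), 154L)
  coh <- sample_cohort(seed = 2)
  counts <- table(coh$group)
  expect_equal(as.integer(counts[gp$group]), gp$n_eyes)
  expect_true(all(table(coh$subject_id) <= 2))
})

test_that("a fixed seed reproduces the cohort exactly", {
  expect_identical(sample_cohort(seed = 42), sample_cohort(seed = 42))
  expect_false(identical(sample_cohort(seed = 42), sample_cohort(seed = 43)))
})

test_that("zero-SD parameters collapse every record onto the group means", {
  gp <- default_group_params()[1, ]
  gp[grep("_sd$", names(gp))] <- 0
  gp$n_eyes <- 6L
  coh <- sample_cohort(gp, seed = 1)
  expect_true(all(coh$volume == gp$volume_mean))
  expect_true(all(coh$axial == gp$axial_mean))
  expect_true(all(coh$se == gp$se_mean))
})

test_that("replicate means of the control group recover the stated volume", {
  gp <- default_group_params()[1, ]
  reps <- vapply(1:120, function(s)
    mean(sample_cohort(gp, seed = 1000 + s)$volume), numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 6182.3), 2 * se + 1e-9)
})

test_that("the copula reproduces the requested volume-eTIV rank correlation", {
  gp <- default_group_params()[1, ]
  gp$n_eyes <- 1000L
  coh <- sample_cohort(gp, seed = 8, eyes_per_subject = 1)
  rho <- cor(coh$volume, coh$etiv, method = "spearman")
  expect_lt(abs(rho - 0.40), 0.05)
})

test_that("sampled marginals are Gaussian with the stated moments", {
  gp <- default_group_params()[1, ]
  gp$n_eyes <- 5000L
  coh <- sample_cohort(gp, seed = 4, eyes_per_subject = 1)
  for (v in c("volume", "axial", "age")) {
    ks <- suppressWarnings(stats::ks.test(
      coh[[v]], "pnorm", mean = gp[[paste0(v, "_mean")]],
      sd = gp[[paste0(v, "_sd")]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("exclusion bounds are enforced by redrawing, not clipping", {
  gp <- default_group_params()[2, ]  # myopia: SE -5.3 +- 1.78, tail below -8
  gp$n_eyes <- 400L
  coh <- sample_cohort(gp, seed = 6, eyes_per_subject = 1)
  expect_true(all(coh$se > -8))
  expect_true(all(coh$volume > 0))
  # redrawing keeps the surviving distribution smooth near the bound:
  # some mass must remain in (-8, -7]
  expect_gt(mean(coh$se <= -7), 0.02)
})

test_that("an invalid correlation specification is rejected", {
  bad <- default_correlation_spec()
  bad["volume", "axial"] <- bad["axial", "volume"] <- 2
  expect_error(sample_cohort(correlation_spec = bad), "invalid correlation spec")
  asym <- default_correlation_spec()
  asym["volume", "axial"] <- 0.1
  expect_error(sample_cohort(correlation_spec = asym),
               "invalid correlation spec")
})

test_that("group assignment follows the refraction and status rules", {
  tab <- tibble::tibble(
    se = c(-5.3, -3.0, -3.01, -8.5, -0.4, -6.0),
    glaucoma = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    ppg = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  out <- assign_groups(tab)
  expect_equal(nrow(out), 5)  # the -8.5 D eye is excluded
  expect_equal(out$group, c("myopia", "control", "myopia", "glaucoma",
                            "glaucoma_myopia"))
  expect_error(assign_groups(tibble::tibble(glaucoma = TRUE)),
               "incomplete record")
  expect_error(assign_groups(tibble::tibble(se = NA_real_, glaucoma = TRUE)),
               "incomplete record")
})

test_that("PPG status takes precedence over the 2x2 grouping", {
  tab <- tibble::tibble(se = c(-5, -1), glaucoma = c(FALSE, FALSE),
                        ppg = c(TRUE, TRUE))
  expect_equal(assign_groups(tab)$group, c("ppg", "ppg"))
})

test_that("glaucoma stage follows the MD severity bins", {
  expect_equal(md_to_stage(c(0, -5.9, -6, -11.9, -12, -19.9, -20, -25)),
               c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L))
  coh <- small_cohort(seed = 3, scale = 0.4)
  expect_true(all(coh$stage[!coh$group %in% c("glaucoma", "glaucoma_myopia")] == 0))
  expect_true(all(coh$stage[coh$group %in% c("glaucoma", "glaucoma_myopia")] >= 1))
})
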