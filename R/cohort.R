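#' Default per-group cohort parameters
#'
#' Group-wise means and SDs of the whole-eye morphometric and demographic
#' variables for the five study groups (normal control, myopia without
#' glaucoma, glaucoma without myopia, glaucoma with myopia, and preperimetric
#' glaucoma), with eye counts 30/13/33/51/27. Units: eye volume mm^3, lengths
#' mm, age years, height cm, eTIV 10^3 mm^3, SE diopters, MD dB, IOP mmHg.
#' `sex_ratio` is the fraction of male eyes.
#'
#' @return a tibble with one row per group and `<var>_mean` / `<var>_sd`
#'   columns for volume, axial, transverse, age, height, etiv, se, md, iop.
#' @export
default_group_params <- function() {
  tibble::tribble(
    ~group, ~n_eyes, ~volume_mean, ~volume_sd, ~axial_mean, ~axial_sd,
    ~transverse_mean, ~transverse_sd, ~age_mean, ~age_sd, ~height_mean,
    ~height_sd, ~etiv_mean, ~etiv_sd, ~se_mean, ~se_sd, ~md_mean, ~md_sd,
    ~iop_mean, ~iop_sd, ~sex_ratio,
    "control",         30L, 6182.3,  909.2, 23.2, 1.3, 23.2, 0.8, 59.7, 9.5,
    160.2, 7.0, 1383.8, 143.3, -0.39, 1.46,   0.54, 1.0,  15.1, 2.6, 12 / 30,
    "myopia",          13L, 7467.6, 1028.6, 25.6, 1.5, 24.3, 1.4, 48.0, 7.0,
    168.6, 5.9, 1506.2, 131.9, -5.30, 1.78,  -0.05, 0.86, 13.3, 1.9,  8 / 13,
    "glaucoma",        33L, 7357.3, 1265.7, 24.6, 1.8, 24.2, 1.4, 57.4, 9.7,
    160.3, 10.0, 1364.2, 125.7, -0.97, 1.03, -10.20, 7.3, 12.8, 2.6, 11 / 33,
    "glaucoma_myopia", 51L, 7558.9,  843.8, 25.2, 1.3, 24.4, 1.1, 54.2, 8.9,
    162.4, 8.5, 1397.1, 99.0, -5.58, 1.84, -10.04, 8.0,  12.7, 2.1, 17 / 49,
    "ppg",             27L, 6888.4,  850.8, 24.4, 1.5, 23.4, 1.3, 57.9, 9.3,
    161.0, 7.0, 1413.7, 122.8, -1.88, 2.65,  -0.25, 1.5,  14.0, 2.8, 12 / 27)
}

cohort_variables <- function() {
  c("volume", "axial", "transverse", "age", "height", "etiv", "se", "md", "iop")
}

#' Default within-group Spearman correlation targets
#'
#' Correlation structure used by [sample_cohort()] for the joint within-group
#' distribution of the nine numeric cohort variables. Volume is strongly
#' coupled to the two diameters it is built from, moderately to the body-size
#' normalizers (height, eTIV: rho 0.40), and refractive error tracks axial
#' elongation negatively; visual-field and pressure variables are left
#' uncorrelated within group (their pooled correlations arise from the group
#' mean differences).
#'
#' @return a symmetric Spearman correlation matrix over
#'   `volume, axial, transverse, age, height, etiv, se, md, iop`.
#' @export
default_correlation_spec <- function() {
  v <- cohort_variables()
  m <- diag(length(v))
  dimnames(m) <- list(v, v)
  set <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set("volume", "axial", 0.75)
  set("volume", "transverse", 0.75)
  set("axial", "transverse", 0.55)
  set("volume", "etiv", 0.40)
  set("volume", "height", 0.40)
  set("height", "etiv", 0.55)
  set("axial", "se", -0.45)
  set("volume", "se", -0.35)
  set("transverse", "se", -0.15)
  m
}

# Spearman -> Pearson under a Gaussian copula.
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Sample a synthetic eye cohort
#'
#' Draws per-eye records group by group from a Gaussian copula with Gaussian
#' marginals: the Spearman targets in `correlation_spec` are converted to
#' latent Pearson correlations via `2*sin(pi*rho/6)`, subjects contribute up
#' to two eyes (age, height, eTIV and sex are shared exactly within subject;
#' eye-level variables are correlated `rho_between_eyes` across the two eyes
#' of a subject), and records violating the exclusion bounds (SE of -8 D or
#' worse, or non-physical non-positive values) are redrawn rather than
#' clipped, preserving the marginal shape elsewhere.
#'
#' Per-subject random streams are derived from the master seed by counter
#' offset, so a subset of groups reproduces its records exactly.
#'
#' @param params group parameter tibble as from [default_group_params()].
#' @param correlation_spec Spearman correlation matrix over the cohort
#'   variables (see [default_correlation_spec()]); must be positive
#'   semidefinite.
#' @param seed master integer seed.
#' @param eyes_per_subject maximum eyes per subject (1 or 2).
#' @param rho_between_eyes latent correlation of eye-level variables across
#'   the two eyes of one subject.
#' @return a tibble, one row per eye: identifiers (`subject_id`, `eye_side`,
#'   `group`), the nine numeric variables, `sex`, `stage` (MD-binned ordinal
#'   for glaucomatous groups), `anisotropy`, and ground-truth diameters
#'   `true_axial` / `true_transverse` for phantom digitization.
#' @export
sample_cohort <- function(params = default_group_params(),
                          correlation_spec = default_correlation_spec(),
                          seed = 1, eyes_per_subject = 2,
                          rho_between_eyes = 0.8) {
  vars <- cohort_variables()
  stopifnot(all(vars %in% rownames(correlation_spec)),
            eyes_per_subject %in% c(1, 2))
  rho_s <- correlation_spec[vars, vars]
  if (any(abs(rho_s - t(rho_s)) > 1e-8) || any(abs(diag(rho_s) - 1) > 1e-8))
    stop("invalid correlation spec: must be symmetric with unit diagonal")
  sigma <- spearman_to_pearson(rho_s)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("invalid correlation spec: matrix is not positive semidefinite")

  subject_level <- c("age", "height", "etiv")
  eye_level <- setdiff(vars, subject_level)
  si <- match(subject_level, vars)
  ei <- match(eye_level, vars)
  s_ss <- sigma[si, si]; s_ee <- sigma[ei, ei]; s_es <- sigma[ei, si]
  reg <- s_es %*% solve(s_ss)                  # conditional mean coefficients
  s_cond <- s_ee - reg %*% t(s_es)             # conditional covariance
  chol_ss <- chol(s_ss + diag(1e-10, length(si)))
  chol_cond <- chol(s_cond + diag(1e-10, length(ei)))

  draw_eye_latent <- function(z_s, shared, lam) {
    # shared component across the subject's eyes + eye-specific component
    mu <- as.vector(reg %*% z_s)
    resid <- sqrt(lam) * shared + sqrt(1 - lam) * as.vector(rnorm(length(ei)) %*% chol_cond)
    mu + resid
  }

  out <- list()
  for (gi in seq_len(nrow(params))) {
    gp <- params[gi, ]
    n_eyes <- gp$n_eyes
    if (n_eyes <= 0) stop("invalid group params: n_eyes must be positive")
    means <- vapply(vars, function(v) gp[[paste0(v, "_mean")]], numeric(1))
    sds <- vapply(vars, function(v) gp[[paste0(v, "_sd")]], numeric(1))
    if (any(sds < 0)) stop("invalid group params: SDs must be non-negative")
    n_subj <- ceiling(n_eyes / eyes_per_subject)
    eyes_left <- n_eyes
    for (s in seq_len(n_subj)) {
      set.seed(derive_seed(seed, gi * 100000 + s))
      k <- min(eyes_per_subject, eyes_left)
      eyes_left <- eyes_left - k
      sides <- if (k == 2) sample(c("left", "right")) else sample(c("left", "right"), 1)
      for (attempt in seq_len(1000)) {
        z_s <- as.vector(rnorm(length(si)) %*% chol_ss)
        shared <- as.vector(rnorm(length(ei)) %*% chol_cond)
        z_eyes <- lapply(seq_len(k), function(e)
          draw_eye_latent(z_s, shared, rho_between_eyes))
        recs <- lapply(z_eyes, function(z_e) {
          z <- numeric(length(vars))
          z[si] <- z_s; z[ei] <- z_e
          setNames(means + sds * z, vars)
        })
        ok <- all(vapply(recs, function(r) {
          r[["se"]] > -8 &&
            all(r[c("volume", "axial", "transverse", "height", "etiv", "iop")] > 0) &&
            r[["age"]] > 0
        }, logical(1)))
        if (ok) break
        if (attempt == 1000)
          stop("could not satisfy exclusion bounds for group ", gp$group)
      }
      sex <- if (runif(1) < gp$sex_ratio) "male" else "female"
      for (e in seq_len(k)) {
        r <- recs[[e]]
        out[[length(out) + 1]] <- tibble::tibble(
          subject_id = sprintf("%s_s%02d", gp$group, s),
          eye_side = sides[e], group = gp$group, sex = sex,
          age = r[["age"]], height = r[["height"]], etiv = r[["etiv"]],
          volume = r[["volume"]], axial = r[["axial"]],
          transverse = r[["transverse"]], se = r[["se"]], md = r[["md"]],
          iop = r[["iop"]])
      }
    }
  }
  tbl <- dplyr::bind_rows(out)
  glaucomatous <- tbl$group %in% c("glaucoma", "glaucoma_myopia")
  tbl$stage <- ifelse(glaucomatous, md_to_stage(tbl$md), 0L)
  tbl$anisotropy <- tbl$axial / tbl$transverse
  tbl$true_axial <- tbl$axial
  tbl$true_transverse <- tbl$transverse
  tbl
}

#' Map visual-field mean deviation to an ordinal glaucoma stage
#'
#' Hodapp-style severity binning of the Humphrey MD index: stage 1 for
#' MD >= -6 dB (early), 2 for \[-12, -6), 3 for \[-20, -12), 4 for worse than
#' -20 dB.
#'
#' @param md mean deviation in dB (more negative = worse field loss).
#' @return integer stages.
#' @export
md_to_stage <- function(md) {
  ifelse(md >= -6, 1L, ifelse(md >= -12, 2L, ifelse(md >= -20, 3L, 4L)))
}

#' Assign study group labels from refraction and disease status
#'
#' Applies the study grouping rules to a cohort table: myopia is a spherical
#' equivalent strictly worse than -3.00 D; eyes with SE of -8.00 D or worse
#' (high myopia) are excluded; preperimetric glaucoma (`ppg`) is kept as its
#' own pool; the remainder fall in the 2x2 of glaucoma-by-myopia.
#'
#' @param table tibble with columns `se` (diopters), `glaucoma` (logical) and
#'   optionally `ppg` (logical).
#' @return the table with a `group` column, high-myopia rows removed and a
#'   logical `myopia` column added.
#' @export
assign_groups <- function(table) {
  if (!"se" %in% names(table) || anyNA(table$se))
    stop("incomplete record: SE is required for every eye")
  if (!"glaucoma" %in% names(table))
    stop("incomplete record: glaucoma status is required")
  ppg <- if ("ppg" %in% names(table)) table$ppg else rep(FALSE, nrow(table))
  keep <- table$se > -8
  table <- table[keep, , drop = FALSE]
  ppg <- ppg[keep]
  myopia <- table$se < -3
  table$myopia <- myopia
  table$group <- dplyr::case_when(
    ppg ~ "ppg",
    table$glaucoma & myopia ~ "glaucoma_myopia",
    table$glaucoma ~ "glaucoma",
    myopia ~ "myopia",
    TRUE ~ "control")
  table
}
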