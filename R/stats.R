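# Cohort statistics: Spearman correlation structure, stratified subsets,
# and the two-factor (glaucoma x myopia) ANOVA with Tukey and Dunnett
# post-hoc tables.

#' Spearman correlation matrix over cohort variables
#'
#' Pairwise-complete Spearman rank correlations (average-rank tie
#' correction, as in [stats::cor()]) with asymptotic t-approximation
#' p-values. Constant variables yield `NA` entries with a warning.
#'
#' @param table cohort tibble.
#' @param variables variables to correlate; defaults to the standard set
#'   (age, sex, height, eTIV, SE, stage, MD, axial, transverse, anisotropy,
#'   volume). `sex` is coded 0/1 if present as character.
#' @return an object of class `correlation_matrix`: `variables`, `rho`,
#'   `p_values`, `n`.
#' @export
spearman_matrix <- function(table,
                            variables = c("age", "sex", "height", "etiv",
                                          "se", "stage", "md", "axial",
                                          "transverse", "anisotropy",
                                          "volume")) {
  variables <- intersect(variables, names(table))
  if (length(variables) < 2) stop("need at least two variables present")
  x <- as.data.frame(table[, variables])
  if ("sex" %in% variables && is.character(x$sex))
    x$sex <- as.numeric(x$sex == "male")
  x <- as.matrix(data.frame(lapply(x, as.numeric)))
  p <- length(variables)
  rho <- matrix(NA_real_, p, p, dimnames = list(variables, variables))
  pv <- rho
  diag(rho) <- 1
  diag(pv) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- stats::complete.cases(x[, c(i, j)])
    n <- sum(ok)
    if (n < 3) stop("need at least 3 complete rows per variable pair")
    xi <- x[ok, i]; xj <- x[ok, j]
    if (sd(xi) == 0 || sd(xj) == 0) {
      warning(sprintf("constant variable in pair (%s, %s); rho undefined",
                      variables[i], variables[j]))
      next
    }
    r <- cor(xi, xj, method = "spearman")
    rho[i, j] <- rho[j, i] <- r
    if (abs(r) >= 1) {
      pv[i, j] <- pv[j, i] <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      pv[i, j] <- pv[j, i] <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(variables = variables, rho = rho, p_values = pv,
                 n = nrow(x)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_matrix> %d variables, %d rows\n",
              length(x$variables), x$n))
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
tidy.correlation_matrix <- function(x, ...) {
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$variables[pairs[, 1]],
    var2 = x$variables[pairs[, 2]],
    rho = x$rho[pairs],
    p_value = x$p_values[pairs])
}

#' Correlations within a cohort stratum
#'
#' Filters the cohort with an expression and computes [spearman_matrix()] on
#' the stratum (e.g. the non-myopic groups only, or excluding preperimetric
#' glaucoma).
#'
#' @param table cohort tibble.
#' @param subset_spec filter expression evaluated in the table (unquoted),
#'   e.g. `group != "ppg"`.
#' @param ... passed to [spearman_matrix()] (e.g. `variables`).
#' @return a `correlation_matrix`.
#' @export
stratified_correlations <- function(table, subset_spec, ...) {
  sub <- dplyr::filter(table, {{ subset_spec }})
  if (nrow(sub) == 0) stop("empty stratum")
  spearman_matrix(sub, ...)
}

#' Two-factor ANOVA of a morphometric outcome
#'
#' Crosses glaucoma and myopia status as two factors over the four study
#' groups (preperimetric glaucoma excluded), tests both main effects and
#' their interaction with type-II sums of squares (the design is
#' unbalanced), and attaches post-hoc tables: Tukey HSD over all six group
#' pairs and Dunnett comparisons of each group against control.
#'
#' @param table cohort tibble with a `group` column using the labels
#'   `control`, `myopia`, `glaucoma`, `glaucoma_myopia` (other labels are
#'   dropped).
#' @param outcome name of the numeric outcome column (string).
#' @return an object of class `eye_anova`: `effects` tibble (term, F, p),
#'   `tukey` tibble, `dunnett` tibble, and the underlying `lm` fit.
#' @export
two_factor_anova <- function(table, outcome) {
  stopifnot(outcome %in% names(table))
  four <- c("control", "myopia", "glaucoma", "glaucoma_myopia")
  tab <- dplyr::filter(table, .data$group %in% four)
  tab$glaucoma <- factor(tab$group %in% c("glaucoma", "glaucoma_myopia"),
                         levels = c(FALSE, TRUE))
  tab$myopia <- factor(tab$group %in% c("myopia", "glaucoma_myopia"),
                       levels = c(FALSE, TRUE))
  cells <- table(tab$glaucoma, tab$myopia)
  if (any(cells == 0)) stop("unbalanced design: empty cell")
  tab$.y <- tab[[outcome]]
  if (sd(tab$.y) == 0) {
    # degenerate outcome: no variance to partition
    zero <- tibble::tibble(
      term = c("glaucoma", "myopia", "glaucoma:myopia"),
      statistic = 0, p_value = 1)
    return(structure(list(outcome = outcome, effects = zero,
                          tukey = tibble::tibble(), dunnett = tibble::tibble(),
                          fit = NULL, n = nrow(tab)),
                     class = "eye_anova"))
  }
  fit <- lm(.y ~ glaucoma * myopia, data = tab)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  keep <- terms != "Residuals"
  effects <- tibble::tibble(
    term = c("glaucoma", "myopia", "glaucoma:myopia"),
    statistic = a2$`F value`[keep],
    p_value = a2$`Pr(>F)`[keep])

  tab$group_f <- factor(tab$group, levels = four)
  one_way <- aov(.y ~ group_f, data = tab)
  tk <- TukeyHSD(one_way)$group_f
  tukey <- tibble::tibble(
    comparison = rownames(tk), estimate = tk[, "diff"],
    conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"])
  dn <- summary(multcomp::glht(one_way, linfct = multcomp::mcp(group_f = "Dunnett")))
  dunnett <- tibble::tibble(
    comparison = names(dn$test$coefficients),
    estimate = unname(dn$test$coefficients),
    statistic = unname(dn$test$tstat),
    adj_p_value = unname(dn$test$pvalues))
  structure(list(outcome = outcome, effects = effects, tukey = tukey,
                 dunnett = dunnett, fit = fit, n = nrow(tab)),
            class = "eye_anova")
}

#' @export
print.eye_anova <- function(x, ...) {
  cat(sprintf("<eye_anova> outcome: %s (n = %d eyes)\n", x$outcome, x$n))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.eye_anova <- function(x, which = c("effects", "tukey", "dunnett"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @export
glance.eye_anova <- function(x, ...) {
  r2 <- if (is.null(x$fit)) NA_real_ else summary(x$fit)$r.squared
  tibble::tibble(outcome = x$outcome, n = x$n,
                 r_squared = r2,
                 interaction_p = x$effects$p_value[x$effects$term == "glaucoma:myopia"])
}
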