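#' Construct a visual-field pattern-deviation map
#'
#' Container for a perimetry pattern-deviation probability map laid out on a
#' grid (e.g. the Humphrey 24-2 pattern), with each tested point classified
#' into one of the probability categories `"<1%"`, `"<5%"`, `">=5%"`.
#' Untested grid cells are `NA`. Each tested point must belong to exactly one
#' hemifield.
#'
#' @param p_values character matrix with entries in
#'   `c("<1%", "<5%", ">=5%", NA)`; rows run superior to inferior.
#' @param hemifield optional character matrix (`"upper"` / `"lower"`)
#'   matching `p_values`; by default rows in the top half of the grid are the
#'   upper hemifield and the rest the lower.
#' @param ght_outside_normal glaucoma-hemifield-test flag.
#' @param psd_beyond_95 pattern-standard-deviation flag (beyond the 95%
#'   normal limit).
#' @return an object of class `visual_field_map`.
#' @export
visual_field_map <- function(p_values, hemifield = NULL,
                             ght_outside_normal = FALSE,
                             psd_beyond_95 = FALSE) {
  stopifnot(is.matrix(p_values))
  ok <- p_values %in% c("<1%", "<5%", ">=5%") | is.na(p_values)
  if (!all(ok)) stop("p_values entries must be '<1%', '<5%', '>=5%' or NA")
  if (is.null(hemifield)) {
    hemifield <- matrix(NA_character_, nrow(p_values), ncol(p_values))
    upper <- seq_len(floor(nrow(p_values) / 2))
    hemifield[upper, ] <- "upper"
    hemifield[setdiff(seq_len(nrow(p_values)), upper), ] <- "lower"
    hemifield[is.na(p_values)] <- NA_character_
  }
  stopifnot(all(dim(hemifield) == dim(p_values)))
  tested <- !is.na(p_values)
  if (any(is.na(hemifield[tested])) ||
      !all(hemifield[tested] %in% c("upper", "lower")))
    stop("every tested point must belong to exactly one hemifield")
  structure(list(p_values = p_values, hemifield = hemifield,
                 ght_outside_normal = isTRUE(ght_outside_normal),
                 psd_beyond_95 = isTRUE(psd_beyond_95)),
            class = "visual_field_map")
}

# 4-connected component labels of a logical matrix; returns a list of
# integer index vectors (matrix cell indices), one per component.
components_4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  comps <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    id <- length(comps) + 1L
    queue <- list(c(i, j))
    lab[i, j] <- id
    cells <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells <- c(cells, (cur[2] - 1L) * nr + cur[1])
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- id
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
    comps[[id]] <- cells
  }
  comps
}

#' Classify a visual field as glaucomatous or normal
#'
#' Implements the Anderson-Patella style rule set on a pattern-deviation
#' probability map. A field is glaucomatous if any of the following holds:
#' (1) within a single hemifield there is a 4-connected cluster of at least
#' three points all depressed below the 5% probability level, at least one of
#' them below 1% -- or a 4-connected cluster of at least two points below 1%;
#' (2) the glaucoma hemifield test is outside normal limits; or (3) the
#' pattern standard deviation is beyond the 95% normal limit.
#'
#' @param vf a [visual_field_map()].
#' @return `"glaucomatous"` or `"normal"`.
#' @export
classify_visual_field <- function(vf) {
  stopifnot(inherits(vf, "visual_field_map"))
  if (vf$ght_outside_normal || vf$psd_beyond_95) return("glaucomatous")
  p <- vf$p_values
  for (h in c("upper", "lower")) {
    inh <- !is.na(vf$hemifield) & vf$hemifield == h
    m5 <- inh & !is.na(p) & p %in% c("<1%", "<5%")
    for (comp in components_4(m5)) {
      if (length(comp) >= 3 && any(p[comp] == "<1%")) return("glaucomatous")
    }
    m1 <- inh & !is.na(p) & p == "<1%"
    for (comp in components_4(m1)) {
      if (length(comp) >= 2) return("glaucomatous")
    }
  }
  "normal"
}
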