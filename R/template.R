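# Group-average eye templates: voxelwise averaging after centroid centering,
# rigid (6-DOF, no scaling) alignment to a blurry initial template, aligned
# re-averaging, then group-wise aligned averaging, Gaussian smoothing and
# thresholding. Shape size differences are part of the signal, so scaling is
# never estimated.

template_grid_shape <- function(masks, pad = 4L) {
  dims <- sapply(masks, function(m) dim(m$voxels))
  as.integer(apply(dims, 1, max) + 2L * pad)
}

#' Voxelwise average of centroid-centered masks
#'
#' Translates each mask (by whole voxels) so its foreground centroid sits at
#' the center of a common grid, then averages the binary volumes voxelwise,
#' yielding a probability volume in `[0, 1]`.
#'
#' @param masks list of [eye_mask] objects on compatible voxel spacings.
#' @param grid_shape common grid (voxel counts); defaults to the largest
#'   input grid plus padding.
#' @return an object of class `eye_template` with fields
#'   `probability_volume`, `voxel_size`, `n_contributing`.
#' @export
voxelwise_average <- function(masks, grid_shape = NULL) {
  if (length(masks) == 0) stop("no masks")
  vs <- masks[[1]]$voxel_size
  for (m in masks) stopifnot(all(abs(m$voxel_size - vs) < 1e-9))
  grid_shape <- grid_shape %||% template_grid_shape(masks)
  acc <- array(0, grid_shape)
  ctr <- (grid_shape + 1) / 2
  for (m in masks) {
    w <- which(m$voxels, arr.ind = TRUE)
    cmean <- colMeans(w)
    shift <- round(ctr - cmean)
    w <- sweep(w, 2, shift, "+")
    keep <- w[, 1] >= 1 & w[, 1] <= grid_shape[1] &
      w[, 2] >= 1 & w[, 2] <= grid_shape[2] &
      w[, 3] >= 1 & w[, 3] <= grid_shape[3]
    w <- w[keep, , drop = FALSE]
    idx <- ((w[, 3] - 1) * grid_shape[2] + (w[, 2] - 1)) * grid_shape[1] + w[, 1]
    acc[idx] <- acc[idx] + 1
  }
  new_eye_template(acc / length(masks), vs, n_contributing = length(masks))
}

new_eye_template <- function(prob, voxel_size, n_contributing,
                             group_label = NA_character_,
                             eye_side = NA_character_, final_mask = NULL) {
  structure(list(probability_volume = prob, voxel_size = voxel_size,
                 n_contributing = n_contributing, group_label = group_label,
                 eye_side = eye_side, final_mask = final_mask),
            class = "eye_template")
}

#' @export
print.eye_template <- function(x, ...) {
  d <- dim(x$probability_volume)
  cat(sprintf("<eye_template> %d x %d x %d @ %.2f mm, %d contributing masks\n",
              d[1], d[2], d[3], x$voxel_size[1], x$n_contributing))
  if (!is.na(x$group_label)) cat("  group:", x$group_label, "\n")
  if (!is.null(x$final_mask))
    cat("  final mask:", sum(x$final_mask), "voxels\n")
  invisible(x)
}

# Objective for rigid alignment: mean template probability sampled at the
# transformed mask foreground points (equivalent to binary correlation up to
# normalization). `pts` are mask foreground points in mm relative to the
# mask centroid; `par` = (tx, ty, tz, rx, ry, rz) in mm / degrees.
align_score <- function(par, pts, template, center_vox) {
  R <- rotation_matrix(par[4:6])
  moved <- pts %*% t(R)
  moved <- sweep(moved, 2, par[1:3], "+")
  vox <- sweep(moved / matrix(template$voxel_size, nrow(moved), 3, byrow = TRUE),
               2, center_vox, "+")
  mean(trilinear(template$probability_volume, vox))
}

#' Rigidly align a mask to a template
#'
#' Estimates the 6-DOF (translation + rotation, no scaling) transform
#' maximizing the mean template probability over the transformed foreground
#' voxels. Initialization matches the mask centroid to the template's
#' probability-weighted centroid and tries both the identity rotation and a
#' principal-axes rotation, keeping the better start; a Nelder-Mead
#' refinement follows. If refinement fails to improve on the initialization
#' the initialization is returned with `warning_flag = TRUE`.
#'
#' @param mask a [eye_mask].
#' @param template an `eye_template`.
#' @param n_points number of foreground points subsampled for the objective.
#' @param maxit Nelder-Mead iteration budget.
#' @return a list: `translation` (mm, template-centered frame), `rotation`
#'   (degrees), `score`, `warning_flag`.
#' @export
rigid_align <- function(mask, template, n_points = 10000, maxit = 400) {
  prob <- template$probability_volume
  if (sum(prob) <= 0) stop("degenerate template")
  # score against a slightly blurred template: a hard binary template makes
  # the objective lock onto the voxel grid (axis-aligned placements sample
  # exact voxel centers) and plateaus; one voxel of smoothing removes both
  template_s <- new_eye_template(gaussian_smooth_3d(prob, 1),
                                 template$voxel_size,
                                 template$n_contributing)
  pts_all <- mask_points_mm(mask)
  cm <- colMeans(pts_all)
  pts <- sweep(pts_all, 2, cm, "-")
  cov_full <- stats::cov(pts)  # before subsampling: near-degenerate
                               # eigenvectors are sensitive to sampling noise
  set.seed(nrow(pts))  # deterministic subsample and jitter
  if (nrow(pts) > n_points)
    pts <- pts[sample(nrow(pts), n_points), , drop = FALSE]
  # jitter each sample uniformly within its voxel (fixed once, so the
  # objective stays deterministic): approximates the volume integral of the
  # template over the mask and removes the spurious grid-coincidence optimum
  # when mask and template share a digitization grid
  pts <- pts + matrix(runif(3 * nrow(pts), -0.5, 0.5), ncol = 3) *
    matrix(mask$voxel_size, nrow(pts), 3, byrow = TRUE)
  d <- dim(prob)
  w <- which(prob > 0, arr.ind = TRUE)
  pw <- prob[prob > 0]
  tmpl_cent_vox <- colSums(w * pw) / sum(pw)
  ctr_vox <- (d + 1) / 2
  t0 <- (tmpl_cent_vox - ctr_vox) * template$voxel_size

  # principal-axes candidate rotation
  pa_angles <- tryCatch({
    cov_m <- cov_full
    tm_pts <- sweep(w, 2, tmpl_cent_vox, "-") *
      matrix(template$voxel_size, nrow(w), 3, byrow = TRUE)
    cov_t <- stats::cov.wt(tm_pts, wt = pw)$cov
    vm <- eigen(cov_m, symmetric = TRUE)$vectors
    vt <- eigen(cov_t, symmetric = TRUE)$vectors
    # resolve eigenvector sign ambiguity toward the smallest rotation
    dots <- colSums(vt * vm)
    for (i in 1:3) if (dots[i] < 0) vm[, i] <- -vm[, i]
    R0 <- vt %*% t(vm)
    if (det(R0) < 0) {
      i_min <- which.min(abs(dots))
      vm[, i_min] <- -vm[, i_min]
      R0 <- vt %*% t(vm)
    }
    # Euler extraction (z-y-x composition used by rotation_matrix)
    ry <- asin(pmin(1, pmax(-1, -R0[3, 1])))
    rx <- atan2(R0[3, 2], R0[3, 3])
    rz <- atan2(R0[2, 1], R0[1, 1])
    c(rx, ry, rz) * 180 / pi
  }, error = function(e) NULL)

  starts <- list(c(t0, 0, 0, 0))
  if (!is.null(pa_angles) && all(is.finite(pa_angles)) &&
      max(abs(pa_angles)) <= 60)  # reject flip-like PA solutions for blobs
    starts <- c(starts, list(c(t0, pa_angles)))
  scores <- vapply(starts, align_score, numeric(1),
                   pts = pts, template = template_s, center_vox = ctr_vox)
  par0 <- starts[[which.max(scores)]]
  init_score <- max(scores)
  ctrl <- list(fnscale = -1, maxit = maxit,
               parscale = c(1, 1, 1, 20, 20, 20))
  opt <- stats::optim(par0, align_score, pts = pts, template = template_s,
                      center_vox = ctr_vox, method = "Nelder-Mead",
                      control = ctrl)
  # restart once from the first optimum; Nelder-Mead simplices collapse
  opt2 <- stats::optim(opt$par, align_score, pts = pts, template = template_s,
                       center_vox = ctr_vox, method = "Nelder-Mead",
                       control = ctrl)
  if (opt2$value > opt$value) opt <- opt2
  if (opt$value >= init_score) {
    list(translation = opt$par[1:3], rotation = opt$par[4:6],
         score = opt$value, warning_flag = FALSE)
  } else {
    list(translation = par0[1:3], rotation = par0[4:6], score = init_score,
         warning_flag = TRUE)
  }
}

#' Resample a mask into a template grid under a rigid transform
#'
#' Applies a [rigid_align()] transform by inverse mapping: each template
#' voxel center is pulled back into the mask and the binary volume sampled
#' trilinearly, giving values in `[0, 1]` suitable for averaging.
#'
#' @param mask a [eye_mask].
#' @param transform result of [rigid_align()].
#' @param template the target `eye_template` (defines grid and spacing).
#' @return a numeric array on the template grid.
#' @export
apply_rigid_transform <- function(mask, transform, template) {
  d <- dim(template$probability_volume)
  ctr_vox <- (d + 1) / 2
  g <- expand_grid_vox(d)
  x_t <- sweep(g, 2, ctr_vox, "-") *
    matrix(template$voxel_size, nrow(g), 3, byrow = TRUE)
  R <- rotation_matrix(transform$rotation)
  # forward: x_t = R x_m + t  =>  x_m = R^T (x_t - t)
  x_m <- sweep(x_t, 2, transform$translation, "-") %*% R
  cm <- colMeans(mask_points_mm(mask))
  x_m <- sweep(x_m, 2, cm, "+")
  vals <- trilinear(mask$voxels + 0, mm_to_voxel(x_m, mask$voxel_size, mask$origin))
  array(vals, d)
}

expand_grid_vox <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

aligned_average <- function(masks, template) {
  acc <- array(0, dim(template$probability_volume))
  flags <- logical(length(masks))
  for (i in seq_along(masks)) {
    tr <- rigid_align(masks[[i]], template)
    flags[i] <- tr$warning_flag
    acc <- acc + apply_rigid_transform(masks[[i]], tr, template)
  }
  list(prob = acc / length(masks), warnings = flags)
}

#' Build a group-average eye template
#'
#' Two-pass aligned averaging: (1) a blurry initial template is the
#' centroid-centered voxelwise average of all masks; (2) every mask is
#' rigidly aligned to it and re-averaged into a sharper global template;
#' (3) the masks of the requested group are aligned to that template and
#' averaged within group; (4) the group average is Gaussian-smoothed
#' (`sigma` mm) and thresholded at `threshold` to give the final smooth
#' group mask. Left and right eyes should be processed in separate calls;
#' no mirroring is applied.
#'
#' @param masks list of [eye_mask] objects (all groups, one eye side).
#' @param groups character vector of group labels parallel to `masks`;
#'   `NULL` treats all masks as one group.
#' @param group the group to build the template for.
#' @param sigma Gaussian smoothing SD in mm (default one voxel).
#' @param threshold probability threshold for the final mask.
#' @param rounds number of global align-average refinement rounds.
#' @return an `eye_template` with `final_mask` set.
#' @export
build_group_template <- function(masks, groups = NULL, group = NULL,
                                 sigma = NULL, threshold = 0.5, rounds = 1) {
  if (length(masks) == 0) stop("no masks")
  groups <- groups %||% rep("all", length(masks))
  group <- group %||% groups[[1]]
  stopifnot(length(groups) == length(masks))
  in_group <- which(groups == group)
  if (length(in_group) < 2) stop("insufficient masks: need at least 2 in group")
  vs <- masks[[1]]$voxel_size
  sigma <- sigma %||% vs[1]

  blurry <- voxelwise_average(masks)
  global <- blurry
  for (r in seq_len(rounds)) {
    global <- new_eye_template(aligned_average(masks, global)$prob, vs,
                               n_contributing = length(masks))
  }
  grp <- aligned_average(masks[in_group], global)
  smoothed <- gaussian_smooth_3d(grp$prob, sigma / vs)
  final <- smoothed >= threshold
  side <- unique(stats::na.omit(sapply(masks[in_group], function(m) m$eye_side)))
  new_eye_template(grp$prob, vs, n_contributing = length(in_group),
                   group_label = group,
                   eye_side = if (length(side) == 1) side else NA_character_,
                   final_mask = final)
}

#' Convert a template's final mask to an eye mask
#'
#' @param template an `eye_template` with a `final_mask`.
#' @param landmarks optional landmarks to attach.
#' @return an [eye_mask] centered at the origin.
#' @export
template_to_mask <- function(template, landmarks = list()) {
  stopifnot(inherits(template, "eye_template"), !is.null(template$final_mask))
  d <- dim(template$final_mask)
  origin <- -(d - 1) / 2 * template$voxel_size
  eye_mask(template$final_mask, voxel_size = template$voxel_size,
           origin = origin, eye_side = template$eye_side,
           landmarks = landmarks)
}
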