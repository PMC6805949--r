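#' Specify a digitized eye phantom
#'
#' Describes an ellipsoidal eyeball phantom with an optional localized
#' posterior protrusion ("bump"), to be digitized on a regular voxel grid by
#' [make_eye_mask()]. The shape frame before rotation has the anteroposterior
#' semi-axis along +y (anterior), mediolateral along x, superoinferior along
#' z. The bump adds a radial offset `A * exp(-theta^2 / (2 w^2))` to the
#' ellipsoid surface, where `theta` is the angle from `bump_direction`
#' (in the unrotated shape frame) and `w = bump_angular_width` in radians.
#'
#' @param semi_axis_ap,semi_axis_ml,semi_axis_si semi-axes in mm
#'   (anteroposterior, mediolateral, superoinferior).
#' @param bump_amplitude protrusion height in mm (`0` gives an exact
#'   ellipsoid).
#' @param bump_direction direction of the protrusion in the shape frame;
#'   normalized internally. Default points infero-nasally for a right eye.
#' @param bump_angular_width angular width of the protrusion, degrees.
#' @param rotation Euler angles in degrees (about x, then y, then z).
#' @param center shape center in mm world coordinates.
#' @param voxel_size isotropic voxel edge, mm.
#' @param grid_shape voxel counts per axis; `NULL` picks the smallest grid
#'   that holds the shape with a 3-voxel margin.
#' @return an object of class `eye_phantom_spec`.
#' @export
eye_phantom_spec <- function(semi_axis_ap, semi_axis_ml, semi_axis_si,
                             bump_amplitude = 0,
                             bump_direction = c(-0.5, -1, -0.5),
                             bump_angular_width = 40,
                             rotation = c(0, 0, 0),
                             center = c(0, 0, 0),
                             voxel_size = 0.7,
                             grid_shape = NULL) {
  semi <- c(semi_axis_ap, semi_axis_ml, semi_axis_si)
  if (any(!is.finite(semi)) || any(semi <= 0))
    stop("invalid spec: semi-axes must be positive")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("invalid spec: voxel_size must be positive")
  if (bump_amplitude < 0) stop("invalid spec: bump_amplitude must be >= 0")
  if (bump_angular_width <= 0) stop("invalid spec: bump_angular_width must be > 0")
  r_bound <- max(semi) + bump_amplitude
  if (is.null(grid_shape)) {
    grid_shape <- rep(2L * ceiling(r_bound / voxel_size) + 7L, 3)
  }
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0))
  spec <- structure(
    list(semi_axis_ap = semi_axis_ap, semi_axis_ml = semi_axis_ml,
         semi_axis_si = semi_axis_si, bump_amplitude = bump_amplitude,
         bump_direction = unit_vector(bump_direction),
         bump_angular_width = bump_angular_width,
         rotation = rotation, center = center,
         voxel_size = voxel_size, grid_shape = grid_shape),
    class = "eye_phantom_spec")
  # require the rotation-safe bounding sphere to sit >= 2 voxels inside the grid
  half_extent <- (grid_shape - 1) / 2 * voxel_size
  if (any(r_bound + 2 * voxel_size > half_extent))
    stop("grid too small: shape plus bump does not fit with a 2-voxel margin")
  spec
}

# Radial surface distance of the (bumped) shape along unit directions `u`
# given in the shape frame; rows of `u` are unit vectors.
phantom_radius <- function(spec, u) {
  a <- spec$semi_axis_ml; b <- spec$semi_axis_ap; cc <- spec$semi_axis_si
  # shape frame: x = ml, y = ap, z = si
  r_ell <- 1 / sqrt((u[, 1] / a)^2 + (u[, 2] / b)^2 + (u[, 3] / cc)^2)
  if (spec$bump_amplitude > 0) {
    ct <- pmin(1, pmax(-1, u %*% spec$bump_direction))
    theta <- acos(ct)
    w <- spec$bump_angular_width * pi / 180
    r_ell <- r_ell + spec$bump_amplitude * exp(-theta^2 / (2 * w^2))
  }
  as.vector(r_ell)
}

#' Digitize an eye phantom to a binary mask
#'
#' Rasterizes the implicit surface of an [eye_phantom_spec()] on its voxel
#' grid. A voxel is foreground iff its center lies inside the (rotated,
#' bumped) surface; no partial-volume weighting is applied, matching the
#' granularity of threshold-contour segmentations. Digitization is
#' deterministic; `seed` is accepted for interface uniformity with the other
#' generators and is unused.
#'
#' Ground-truth landmarks are attached to the returned mask: `apex` (anterior
#' pole) and `disk` (posterior pole, on the bumped surface if the bump points
#' posteriorly), both in mm world coordinates.
#'
#' @param spec an [eye_phantom_spec()].
#' @param seed unused; present for a uniform generator interface.
#' @param eye_side optional side tag carried on the mask.
#' @return an [eye_mask] with `landmarks$apex` and `landmarks$disk`.
#' @export
make_eye_mask <- function(spec, seed = NULL, eye_side = NA_character_) {
  stopifnot(inherits(spec, "eye_phantom_spec"))
  g <- spec$grid_shape
  vs <- spec$voxel_size
  origin <- spec$center - (g - 1) / 2 * vs
  # voxel centers in world mm, then into the shape frame
  xs <- origin[1] + (seq_len(g[1]) - 1) * vs
  ys <- origin[2] + (seq_len(g[2]) - 1) * vs
  zs <- origin[3] + (seq_len(g[3]) - 1) * vs
  pts <- cbind(rep(xs, times = g[2] * g[3]),
               rep(rep(ys, each = g[1]), times = g[3]),
               rep(zs, each = g[1] * g[2]))
  R <- rotation_matrix(spec$rotation)
  y <- sweep(pts, 2, spec$center, "-") %*% R  # = t(R) applied to rows
  rr <- sqrt(rowSums(y^2))
  u <- y / pmax(rr, .Machine$double.eps)
  inside <- rr <= phantom_radius(spec, u)
  inside[rr < .Machine$double.eps] <- TRUE
  voxels <- array(inside, g)

  apex_shape <- c(0, spec$semi_axis_ap, 0)
  post_dir <- c(0, -1, 0)
  post_r <- phantom_radius(spec, matrix(post_dir, ncol = 3))
  pole_shape <- post_dir * post_r
  landmarks <- list(
    apex = as.vector(spec$center + R %*% apex_shape),
    disk = as.vector(spec$center + R %*% pole_shape))
  eye_mask(voxels, voxel_size = vs, origin = origin, eye_side = eye_side,
           landmarks = landmarks)
}

#' Generate one phantom mask per cohort record
#'
#' Digitizes an ellipsoid phantom for every eye in a cohort table, using the
#' record's ground-truth diameters (`true_axial` anteroposteriorly,
#' `true_transverse` for both equatorial axes). Each record receives a random
#' rotation of at most `max_rotation` degrees per axis; eyes in glaucoma
#' groups additionally carry an infero-nasal posterior protrusion, mirrored
#' across the midline for left versus right eyes.
#'
#' @param table a cohort tibble from [sample_cohort()] (needs `true_axial`,
#'   `true_transverse`, `group`, `eye_side`).
#' @param seed master seed; per-record generator streams are derived from it,
#'   so any subset of records reproduces its masks.
#' @param voxel_size isotropic voxel edge, mm.
#' @param bump_amplitude protrusion height (mm) applied to glaucoma-group
#'   phantoms.
#' @param max_rotation per-axis rotation bound, degrees.
#' @return a named list of [eye_mask] objects (names = `<subject_id>_<side>`).
#' @export
masks_from_cohort <- function(table, seed = 1, voxel_size = 0.7,
                              bump_amplitude = 0.8, max_rotation = 15) {
  if (nrow(table) == 0) return(list())
  need <- c("true_axial", "true_transverse")
  if (!all(need %in% names(table)) ||
      any(!is.finite(table$true_axial)) || any(!is.finite(table$true_transverse)) ||
      any(table$true_axial <= 0) || any(table$true_transverse <= 0))
    stop("incomplete record: true_axial and true_transverse must be positive")
  masks <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    rec <- table[i, ]
    set.seed(derive_seed(seed, i))
    rot <- runif(3, -max_rotation, max_rotation)
    glaucomatous <- rec$group %in% c("glaucoma", "glaucoma_myopia", "ppg")
    nasal_x <- if (identical(rec$eye_side, "left")) 0.5 else -0.5
    spec <- eye_phantom_spec(
      semi_axis_ap = rec$true_axial / 2,
      semi_axis_ml = rec$true_transverse / 2,
      semi_axis_si = rec$true_transverse / 2,
      bump_amplitude = if (glaucomatous) bump_amplitude else 0,
      bump_direction = c(nasal_x, -1, -0.5),
      rotation = rot,
      voxel_size = voxel_size)
    masks[[i]] <- make_eye_mask(spec, eye_side = rec$eye_side)
  }
  names(masks) <- paste0(table$subject_id, "_", table$eye_side)
  masks
}
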