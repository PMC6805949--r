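# Whole-eye morphometry from a binary mask. The measurement frame follows
# the clinical construction: the eye axis is the normal of the corneal
# tangent plane at the apex, the axial plane contains the corneal apex and
# the optic disk and spans the mediolateral direction, axial length runs
# from the apex to the posterior retina along the eye axis, and the
# transverse length is the widest chord orthogonal to the eye axis within
# the axial plane.

#' Extract the subvoxel surface of a binary mask
#'
#' Returns the level-0.5 isosurface of the binary grid as a point set: the
#' midpoints of every face between a foreground voxel and a 6-neighbor
#' background voxel, in mm world coordinates. For binary data these midpoints
#' are exactly the points where trilinear interpolation crosses 0.5 along
#' grid axes, giving subvoxel localization without a full triangulation.
#'
#' @param mask a valid [eye_mask].
#' @return an `n x 3` matrix of mm coordinates.
#' @export
extract_surface <- function(mask) {
  validate_eye_mask(mask)
  if (sum(mask$voxels) < 2)
    stop("invalid mask: a single-voxel mask has no usable surface")
  v <- mask$voxels
  d <- dim(v)
  pts <- list()
  shift_pairs <- list(
    list(axis = 1, dir = +1), list(axis = 1, dir = -1),
    list(axis = 2, dir = +1), list(axis = 2, dir = -1),
    list(axis = 3, dir = +1), list(axis = 3, dir = -1))
  for (sp in shift_pairs) {
    nb <- array(FALSE, d)
    if (sp$axis == 1) {
      if (sp$dir > 0) nb[1:(d[1] - 1), , ] <- v[2:d[1], , ]
      else nb[2:d[1], , ] <- v[1:(d[1] - 1), , ]
    } else if (sp$axis == 2) {
      if (sp$dir > 0) nb[, 1:(d[2] - 1), ] <- v[, 2:d[2], ]
      else nb[, 2:d[2], ] <- v[, 1:(d[2] - 1), ]
    } else {
      if (sp$dir > 0) nb[, , 1:(d[3] - 1)] <- v[, , 2:d[3]]
      else nb[, , 2:d[3]] <- v[, , 1:(d[3] - 1)]
    }
    face <- which(v & !nb, arr.ind = TRUE)  # fg voxel whose neighbor is bg
    if (nrow(face) == 0) next
    mid <- face - 1
    mid[, sp$axis] <- mid[, sp$axis] + sp$dir * 0.5
    pts[[length(pts) + 1]] <- sweep(
      sweep(mid, 2, mask$voxel_size, "*"), 2, mask$origin, "+")
  }
  do.call(rbind, pts)
}

#' Locate the corneal apex
#'
#' The apex ("top of the cornea") is an anatomical landmark: when the mask
#' carries an `apex` landmark (phantom ground truth or a sidecar
#' annotation), that point is returned. Otherwise the apex is taken as the
#' surface point with the maximal anterior (+y) coordinate -- adequate for
#' eyes imaged in near-anterior gaze -- with exact ties resolved by the
#' centroid of the tied set, which centers the apex on flat digitization
#' plateaus.
#'
#' @param mask a valid [eye_mask].
#' @param surface optional precomputed [extract_surface()] output.
#' @return mm point (length 3).
#' @export
find_corneal_apex <- function(mask, surface = NULL) {
  if (!is.null(mask$landmarks$apex)) return(mask$landmarks$apex)
  if (is.null(surface)) surface <- extract_surface(mask)
  ymax <- max(surface[, 2])
  tied <- surface[surface[, 2] >= ymax - 1e-9, , drop = FALSE]
  colMeans(tied)
}

#' Locate the optic-disk point
#'
#' A binary mask carries no disk anatomy, so the disk point is taken from the
#' mask's `disk` landmark when one is supplied (e.g. phantom ground truth or
#' a sidecar annotation). Otherwise the documented fallback is the posterior
#' pole: the surface point at maximal Euclidean distance from the corneal
#' apex (ties resolved by centroid).
#'
#' @param mask a valid [eye_mask].
#' @param apex apex point from [find_corneal_apex()]; computed if missing.
#' @param surface optional precomputed surface point set.
#' @return mm point (length 3).
#' @export
find_optic_disk <- function(mask, apex = NULL, surface = NULL) {
  if (!is.null(mask$landmarks$disk)) return(mask$landmarks$disk)
  if (is.null(surface)) surface <- extract_surface(mask)
  if (is.null(apex)) apex <- find_corneal_apex(mask, surface)
  d2 <- rowSums(sweep(surface, 2, apex, "-")^2)
  tied <- surface[d2 >= max(d2) - 1e-9, , drop = FALSE]
  colMeans(tied)
}

#' Build the measurement axis frame
#'
#' Fits the corneal tangent plane by total least squares to the surface
#' points within `cap_radius` (default 4 mm) of the apex; the eye axis is that plane's
#' normal through the apex, oriented towards the mask centroid (posteriorly).
#' The axial plane is the plane through apex and disk whose normal is
#' orthogonal to the anatomical left-right axis, i.e. the tilted transverse
#' plane spanning the apex-disk line and the mediolateral direction.
#'
#' @param mask a valid [eye_mask].
#' @param apex,disk mm points; computed from the mask when missing.
#' @param cap_radius radius (mm) of the corneal cap used for the tangent fit.
#' @param surface optional precomputed surface point set.
#' @return an object of class `axis_frame`: `apex`, `disk`, `eye_axis`
#'   (unit, pointing posteriorly), `plane_normal` (unit, axial plane through
#'   the apex), `in_plane` (unit vector orthogonal to the eye axis within the
#'   axial plane).
#' @export
build_axis_frame <- function(mask, apex = NULL, disk = NULL, cap_radius = 4,
                             surface = NULL) {
  if (is.null(surface)) surface <- extract_surface(mask)
  if (is.null(apex)) apex <- find_corneal_apex(mask, surface)
  if (is.null(disk)) disk <- find_optic_disk(mask, apex, surface)
  if (sqrt(sum((disk - apex)^2)) < 5)
    stop("degenerate landmarks: apex and disk are less than 5 mm apart")
  cap <- surface[rowSums(sweep(surface, 2, apex, "-")^2) <= cap_radius^2, ,
                 drop = FALSE]
  if (nrow(cap) < 4) stop("invalid mask: too few surface points near the apex")
  centered <- sweep(cap, 2, colMeans(cap), "-")
  sv <- svd(centered, nu = 0)
  normal <- sv$v[, 3]  # direction of least variance = tangent-plane normal
  centroid <- mask_centroid_mm(mask)
  if (sum(normal * (centroid - apex)) < 0) normal <- -normal
  eye_axis <- unit_vector(normal)
  ml <- c(1, 0, 0)
  plane_normal <- unit_vector(cross3(disk - apex, ml))
  in_plane <- unit_vector(cross3(plane_normal, eye_axis))
  structure(list(apex = apex, disk = disk, eye_axis = eye_axis,
                 plane_normal = plane_normal, in_plane = in_plane),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("<axis_frame>\n")
  cat(sprintf("  apex: (%.2f, %.2f, %.2f) mm\n", x$apex[1], x$apex[2], x$apex[3]))
  cat(sprintf("  disk: (%.2f, %.2f, %.2f) mm\n", x$disk[1], x$disk[2], x$disk[3]))
  cat(sprintf("  eye axis: (%.3f, %.3f, %.3f)\n",
              x$eye_axis[1], x$eye_axis[2], x$eye_axis[3]))
  invisible(x)
}

# March along start + t*dir (t in [0, t_max]) through the trilinearly
# interpolated binary grid and return the last downcrossing of 0.5, linearly
# refined. NA if the ray never enters the mask.
last_surface_crossing <- function(mask, start, dir, t_max, step = NULL) {
  step <- step %||% (min(mask$voxel_size) / 10)
  tt <- seq(0, t_max, by = step)
  pts <- cbind(start[1] + tt * dir[1], start[2] + tt * dir[2],
               start[3] + tt * dir[3])
  vals <- trilinear(mask$voxels + 0, mm_to_voxel(pts, mask$voxel_size, mask$origin))
  inside <- vals >= 0.5
  if (!any(inside)) return(NA_real_)
  i <- max(which(inside))
  if (i == length(tt)) return(tt[i])
  # refine between samples i (>= 0.5) and i+1 (< 0.5)
  f <- (vals[i] - 0.5) / (vals[i] - vals[i + 1])
  tt[i] + f * step
}

#' Measure the axial length
#'
#' Distance from the corneal apex to the posterior retina: the last
#' intersection of the posterior ray along the eye axis with the level-0.5
#' isosurface. Taking the last crossing makes the measurement robust to
#' local concavities around posterior protrusions.
#'
#' @param mask a valid [eye_mask].
#' @param frame an `axis_frame` from [build_axis_frame()].
#' @return length in mm.
#' @export
measure_axial_length <- function(mask, frame) {
  d <- dim(mask$voxels) * mask$voxel_size
  len <- last_surface_crossing(mask, frame$apex, frame$eye_axis,
                               t_max = sqrt(sum(d^2)))
  if (!is.finite(len) || len <= min(mask$voxel_size))
    stop("axis leaves mask: no posterior intersection along the eye axis")
  len
}

#' Measure the transverse length
#'
#' The maximum, over positions along the eye axis, of the chord of the
#' level-0.5 isosurface taken orthogonally to the eye axis. By default the
#' chord is confined to the axial plane (the clinical measurement plane);
#' with `transverse_3d = TRUE` the chord direction is additionally maximized
#' over all directions orthogonal to the eye axis.
#'
#' @param mask a valid [eye_mask].
#' @param frame an `axis_frame`.
#' @param transverse_3d take the 3D maximal orthogonal chord instead of the
#'   in-axial-plane chord.
#' @param n_axis number of probing stations along the eye axis.
#' @param n_angles number of chord directions probed when `transverse_3d`.
#' @return length in mm.
#' @export
measure_transverse_length <- function(mask, frame, transverse_3d = FALSE,
                                      n_axis = 120, n_angles = 36) {
  axial <- measure_axial_length(mask, frame)
  tt <- seq(0, axial, length.out = n_axis)
  dirs <- if (transverse_3d) {
    u2 <- unit_vector(cross3(frame$eye_axis, frame$in_plane))
    lapply(seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)],
           function(a) cos(a) * frame$in_plane + sin(a) * u2)
  } else {
    list(frame$in_plane)
  }
  best <- 0
  d <- dim(mask$voxels) * mask$voxel_size
  t_max <- max(d)
  for (u in dirs) {
    chord <- vapply(tt, function(t0) {
      p0 <- frame$apex + t0 * frame$eye_axis
      s_pos <- last_surface_crossing(mask, p0, u, t_max)
      s_neg <- last_surface_crossing(mask, p0, -u, t_max)
      if (is.na(s_pos) || is.na(s_neg)) return(NA_real_)
      s_pos + s_neg
    }, numeric(1))
    if (all(is.na(chord))) next
    best <- max(best, max(chord, na.rm = TRUE))
  }
  if (best <= 0) stop("axis leaves mask: no transverse chord found")
  best
}

#' Eyeball volume of a binary mask
#'
#' Foreground voxel count times voxel volume, matching the granularity of
#' contour-based segmentation tools.
#'
#' @param mask a valid [eye_mask].
#' @return volume in mm^3.
#' @export
compute_volume <- function(mask) {
  validate_eye_mask(mask)
  sum(mask$voxels) * prod(mask$voxel_size)
}

#' Measure a whole eye
#'
#' Runs the full measurement chain on one mask: surface extraction, apex and
#' disk localization, axis-frame construction, then volume, axial length,
#' transverse length and the anisotropy ratio (axial / transverse; 1 =
#' spherical, above 1 = anteroposteriorly elongated).
#'
#' @param mask a valid [eye_mask].
#' @param transverse_3d see [measure_transverse_length()].
#' @return a one-row tibble with columns `volume`, `axial_length`,
#'   `transverse_length`, `anisotropy` and the landmark coordinates; the
#'   `axis_frame` is attached as attribute `"frame"` for audit.
#' @export
measure_eye <- function(mask, transverse_3d = FALSE) {
  validate_eye_mask(mask)
  surface <- extract_surface(mask)
  apex <- find_corneal_apex(mask, surface)
  disk <- find_optic_disk(mask, apex, surface)
  frame <- build_axis_frame(mask, apex, disk, surface = surface)
  vol <- sum(mask$voxels) * prod(mask$voxel_size)
  axial <- measure_axial_length(mask, frame)
  transverse <- measure_transverse_length(mask, frame,
                                          transverse_3d = transverse_3d)
  res <- tibble::tibble(
    volume = vol, axial_length = axial, transverse_length = transverse,
    anisotropy = axial / transverse,
    apex_x = apex[1], apex_y = apex[2], apex_z = apex[3],
    disk_x = disk[1], disk_y = disk[2], disk_z = disk[3])
  attr(res, "frame") <- frame
  res
}

#' Measure every mask of a cohort
#'
#' @param masks named list of [eye_mask] objects (as from
#'   [masks_from_cohort()]).
#' @param transverse_3d see [measure_transverse_length()].
#' @return a tibble with one row per mask, the mask name in `mask_id`.
#' @export
measure_cohort <- function(masks, transverse_3d = FALSE) {
  rows <- purrr::imap(masks, function(m, id)
    dplyr::mutate(measure_eye(m, transverse_3d = transverse_3d),
                  mask_id = id, .before = 1))
  dplyr::bind_rows(rows)
}
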