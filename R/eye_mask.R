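#' Binary eye mask volume
#'
#' Lightweight container for a 3D binary eyeball segmentation. Grid axis 1 is
#' the subject's left-right axis (+x = right), axis 2 anteroposterior
#' (+y = anterior), axis 3 superoinferior (+z = superior); all world
#' coordinates are in mm.
#'
#' @param voxels 3D logical or 0/1 array.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param origin mm coordinates of the center of voxel `[1, 1, 1]`.
#' @param eye_side `"left"`, `"right"`, or `NA`.
#' @param landmarks optional named list of mm points (e.g. `apex`, `disk`).
#' @return an object of class `eye_mask`.
#' @export
eye_mask <- function(voxels, voxel_size = 0.7, origin = c(0, 0, 0),
                     eye_side = NA_character_, landmarks = list()) {
  stopifnot(length(dim(voxels)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0), length(origin) == 3)
  storage.mode(voxels) <- "logical"
  structure(
    list(voxels = voxels, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), eye_side = eye_side,
         landmarks = landmarks),
    class = "eye_mask")
}

#' @export
print.eye_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<eye_mask> %d x %d x %d voxels @ %.2f x %.2f x %.2f mm, %d foreground\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], sum(x$voxels)))
  if (!is.na(x$eye_side)) cat("  eye side:", x$eye_side, "\n")
  if (length(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an eye mask
#'
#' Checks the structural invariants every measurement assumes: a non-empty
#' foreground forming exactly one 26-connected component, with more than one
#' voxel, that does not touch any face of the grid.
#'
#' @param mask an [eye_mask].
#' @return the mask, invisibly; otherwise an error.
#' @export
validate_eye_mask <- function(mask) {
  stopifnot(inherits(mask, "eye_mask"))
  v <- mask$voxels
  n_fg <- sum(v)
  if (n_fg < 1) stop("invalid mask: empty foreground")
  d <- dim(v)
  if (any(v[1, , ]) || any(v[d[1], , ]) || any(v[, 1, ]) || any(v[, d[2], ]) ||
      any(v[, , 1]) || any(v[, , d[3]]))
    stop("invalid mask: foreground touches the grid boundary")
  cc <- connected_components_26(v)
  if (cc$n_components != 1)
    stop(sprintf("invalid mask: expected one connected component, found %d",
                 cc$n_components))
  invisible(mask)
}

# Foreground voxel centers in mm.
mask_points_mm <- function(mask) {
  voxel_centers_mm(mask$voxels, mask$voxel_size, mask$origin)
}

mask_centroid_mm <- function(mask) {
  colMeans(mask_points_mm(mask))
}
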