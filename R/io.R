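# NIfTI and CSV I/O. Masks are stored as 0/1 integer NIfTI volumes with an
# axis-aligned RAS affine (anterior = +y); landmarks travel in a JSON
# sidecar next to the image.

landmark_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".landmarks.json", path)
}

#' Write an eye mask as NIfTI
#'
#' Writes the binary volume with an RAS mm affine (diagonal voxel scaling
#' plus the origin translation). Landmarks, if present, are written to a
#' `<name>.landmarks.json` sidecar.
#'
#' @param mask an [eye_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_eye_mask <- function(mask, path) {
  stopifnot(inherits(mask, "eye_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$voxel_size  # before sform: scale would be dropped
  affine <- rbind(cbind(diag(mask$voxel_size), mask$origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  if (length(mask$landmarks) > 0) {
    jsonlite::write_json(
      c(mask$landmarks, list(eye_side = mask$eye_side)),
      landmark_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an eye mask from NIfTI
#'
#' Requires an axis-aligned affine (no obliquity); voxel spacing and origin
#' are taken from it. Non-binary volumes are binarized at 0.5 with a
#' warning. A `<name>.landmarks.json` sidecar, when present, supplies the
#' landmarks.
#'
#' @param path NIfTI file.
#' @param eye_side optional side tag; overrides any sidecar value.
#' @return an [eye_mask].
#' @export
read_eye_mask <- function(path, eye_side = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  affine <- RNifti::xform(img)
  rot <- affine[1:3, 1:3]
  off_diag <- rot - diag(diag(rot))
  if (any(abs(off_diag) > 1e-4 * max(abs(diag(rot)))) || any(diag(rot) <= 0))
    stop("oblique or non-RAS affine in ", path,
         "; eye masks must be axis-aligned with positive spacings")
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D volume in ", path)
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1))) {
    warning("non-binary volume in ", path, "; binarizing at 0.5")
    arr <- arr >= 0.5
  }
  landmarks <- list()
  side <- eye_side
  sc <- landmark_sidecar_path(path)
  if (file.exists(sc)) {
    lj <- jsonlite::read_json(sc, simplifyVector = TRUE)
    side <- side %||% lj$eye_side
    lj$eye_side <- NULL
    landmarks <- lapply(lj, as.numeric)
  }
  eye_mask(arr > 0.5, voxel_size = diag(rot), origin = affine[1:3, 4],
           eye_side = side %||% NA_character_, landmarks = landmarks)
}

#' Write / read a cohort table as CSV
#'
#' One row per eye, snake_case columns, units as in
#' [default_group_params()].
#'
#' @param table cohort tibble.
#' @param path CSV path.
#' @return `path` / a tibble.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Export a template surface as PLY
#'
#' Writes the level-0.5 surface point set of a template's final mask (face
#' midpoints, with per-point outward normals along the face directions) as
#' an ASCII PLY point cloud for external rendering.
#'
#' @param template an `eye_template` with `final_mask`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_template_surface <- function(template, path) {
  mask <- template_to_mask(template)
  pts <- extract_surface(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(pts, trim = TRUE, digits = 6), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
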