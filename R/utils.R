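# Small geometry and array helpers shared across the package.
# World coordinate convention throughout: +x = right, +y = anterior,
# +z = superior (RAS); voxel (i, j, k) has its center at
# origin + (c(i, j, k) - 1) * voxel_size, all in mm.

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations about the x, then y, then z world axes (applied as
#' `Rz %*% Ry %*% Rx`), angles in degrees.
#'
#' @param angles numeric length-3, degrees about x, y, z.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Trilinear interpolation of a 3D array at continuous (1-based) voxel
# coordinates. Points outside the grid return `outside`.
trilinear <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v000 <- arr[idx(x0, y0, z0)];         v100 <- arr[idx(x0 + 1, y0, z0)]
  v010 <- arr[idx(x0, y0 + 1, z0)];     v110 <- arr[idx(x0 + 1, y0 + 1, z0)]
  v001 <- arr[idx(x0, y0, z0 + 1)];     v101 <- arr[idx(x0 + 1, y0, z0 + 1)]
  v011 <- arr[idx(x0, y0 + 1, z0 + 1)]; v111 <- arr[idx(x0 + 1, y0 + 1, z0 + 1)]
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  out[ok] <- v0 * (1 - fz) + v1 * fz
  out
}

# Voxel-center coordinates (mm) of the TRUE voxels of a logical/0-1 array.
voxel_centers_mm <- function(voxels, voxel_size, origin) {
  w <- which(voxels > 0.5, arr.ind = TRUE)
  sweep(sweep(w - 1, 2, voxel_size, "*"), 2, origin, "+")
}

mm_to_voxel <- function(pts, voxel_size, origin) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, origin, "-"), 2, voxel_size, "/") + 1
}

voxel_to_mm <- function(pts, voxel_size, origin) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts - 1, 2, voxel_size, "*"), 2, origin, "+")
}

# Largest 26-connected foreground component count and membership, by BFS on
# linear indices of a zero-padded copy (padding makes neighbor offsets safe).
connected_components_26 <- function(voxels) {
  d <- dim(voxels)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- voxels > 0.5
  dp <- dim(pad)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_off <- offs[, 1] + dp[1] * offs[, 2] + dp[1] * dp[2] * offs[, 3]
  fg <- which(pad)
  if (length(fg) == 0) return(list(n_components = 0L, labels = integer(0)))
  visited <- logical(length(pad))
  comp <- 0L
  remaining <- fg
  repeat {
    remaining <- remaining[!visited[remaining]]
    if (length(remaining) == 0) break
    comp <- comp + 1L
    frontier <- remaining[1]
    visited[frontier] <- TRUE
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, lin_off, "+")))
      nb <- nb[pad[nb] & !visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
  }
  list(n_components = comp, n_foreground = length(fg))
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
gaussian_smooth_3d <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  d <- dim(arr)
  smooth_one <- function(n, s) {
    if (s <= 0) return(diag(n))
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half):half)^2 / (2 * s^2))
    m <- matrix(0, n, n)
    for (o in (-half):half) {
      idx <- seq_len(n)
      tgt <- idx + o
      keep <- tgt >= 1 & tgt <= n
      m[cbind(idx[keep], tgt[keep])] <- k[o + half + 1]
    }
    m / rowSums(m)  # renormalize at edges
  }
  # axis 1
  a <- matrix(arr, d[1], d[2] * d[3])
  a <- smooth_one(d[1], sigma_vox[1]) %*% a
  arr <- array(a, d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  a <- matrix(arr, d[2], d[1] * d[3])
  a <- smooth_one(d[2], sigma_vox[2]) %*% a
  arr <- aperm(array(a, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 1, 2))
  a <- matrix(arr, d[3], d[1] * d[2])
  a <- smooth_one(d[3], sigma_vox[3]) %*% a
  aperm(array(a, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Dice overlap coefficient between two binary volumes
#'
#' @param a,b binary arrays of identical dimensions.
#' @return `2|A∩B| / (|A| + |B|)`, in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a > 0.5; b <- b > 0.5
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Derive a per-stream seed from a master seed; kept within 32-bit range.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset * 7919) %% 2147483587) + 1L
}
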