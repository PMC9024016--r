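#' World / voxel coordinate mapping
#'
#' Voxel indices are 0-based integer triples; `voxelToWorld` maps a
#' (possibly continuous) voxel coordinate to world mm via the grid affine,
#' `worldToVoxel` applies the inverse affine. Both accept a single 3-vector
#' or an n x 3 matrix of points.
#'
#' @param points numeric 3-vector or n x 3 matrix.
#' @param grid a [VolumeGrid-class].
#' @return Coordinates in the target system, same shape as the input.
#' @export
worldToVoxel <- function(points, grid) {
  pts <- asPointMatrix(points)
  if (any(!is.finite(pts))) stop("points must be finite world coordinates")
  inv <- solve(grid@affine)
  out <- t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
  if (is.matrix(points)) out else drop(out)
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(points, grid) {
  pts <- asPointMatrix(points)
  if (any(!is.finite(pts))) stop("points must be finite voxel coordinates")
  out <- t(grid@affine[1:3, 1:3] %*% t(pts) + grid@affine[1:3, 4])
  if (is.matrix(points)) out else drop(out)
}

asPointMatrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("point matrix must have 3 columns")
    points
  } else {
    if (length(points) != 3L) stop("a point must have 3 coordinates")
    matrix(as.numeric(points), 1L, 3L)
  }
}

#' Nearest voxel under the voxel-centre convention
#'
#' A continuous voxel coordinate belongs to integer index `i` iff it lies in
#' the half-open cell `[i - 0.5, i + 0.5)` on every axis. Coordinates whose
#' index falls outside the grid on any axis yield `NA` for that point (the
#' out-of-grid marker).
#'
#' @param pointsVox continuous voxel coordinates, 3-vector or n x 3 matrix.
#' @param grid a [VolumeGrid-class].
#' @return Integer voxel indices (0-based), same shape as the input, with
#'   all-`NA` rows marking out-of-grid points.
#' @export
nearestVoxel <- function(pointsVox, grid) {
  pts <- asPointMatrix(pointsVox)
  idx <- floor(pts + 0.5)
  bad <- idx[, 1] < 0 | idx[, 1] >= grid@shape[1] |
         idx[, 2] < 0 | idx[, 2] >= grid@shape[2] |
         idx[, 3] < 0 | idx[, 3] >= grid@shape[3]
  idx[bad, ] <- NA_real_
  storage.mode(idx) <- "integer"
  if (is.matrix(pointsVox)) idx else drop(idx)
}

# 0-based voxel triples (rows) -> 1-based linear array index
voxelLinear <- function(idx, shape) {
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 3L)
  1L + idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3])
}

# 1-based linear array index -> 0-based voxel triples (rows)
linearVoxel <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i, j, k, deparse.level = 0)
}

# grids must agree exactly in shape, affine within 1e-6
checkSameGrid <- function(a, b, what = "volumes") {
  if (!identical(a@shape, b@shape) ||
      max(abs(a@affine - b@affine)) > 1e-6)
    stop(what, " must share an identical grid (no implicit resampling)")
  invisible(TRUE)
}
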