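#' Lesion-overlap score of a single fiber
#'
#' The number of lesion voxels among the voxels the streamline passes
#' through (set semantics: a voxel traversed twice counts once).
#'
#' @param s an n x 3 matrix of world-mm points.
#' @param lesion a [BinaryMask-class] on the tractogram's reference grid.
#' @param grid the reference [VolumeGrid-class] (defaults to the lesion's).
#' @return A non-negative integer.
#' @export
fiberLesionScore <- function(s, lesion, grid = lesion@grid) {
  checkSameGrid(grid, lesion@grid, "lesion mask and reference grid")
  path <- streamlineVoxelPath(s, grid)
  if (nrow(path) == 0L) return(0L)
  sum(lesion@data[voxelLinear(path, grid@shape)] != 0)
}

#' Lesion-overlap scores for every fiber of a tractogram
#'
#' @param t a [Tractogram-class].
#' @param lesion a [BinaryMask-class] on the same grid.
#' @return Integer vector, one score per fiber.
#' @export
fiberScores <- function(t, lesion) {
  checkSameGrid(t@grid, lesion@grid, "tractogram and lesion mask")
  pp <- tractogramPaths(t)
  scoresFromPaths(pp$paths, lesion)
}

scoresFromPaths <- function(paths, lesion) {
  inLesion <- as.vector(lesion@data != 0)
  vapply(paths, function(p) sum(inLesion[p]), integer(1))
}

#' Project fiber scores to fiber endpoints
#'
#' Builds a zero-initialized volume and, for every fiber with score s > 0,
#' adds s at each of its two endpoint voxels (coincident endpoints
#' accumulate; out-of-grid endpoints are skipped). Fibers with score 0
#' contribute nothing, so when every endpoint is in-grid the image total is
#' exactly twice the sum of the scores.
#'
#' @param t a [Tractogram-class].
#' @param scores non-negative numeric vector, one score per fiber.
#' @return A [ScalarVolume-class] (the raw, unsmoothed endpoint image).
#' @export
endpointImage <- function(t, scores) {
  if (length(scores) != nStreamlines(t))
    stop("need exactly one score per fiber (", nStreamlines(t), " fibers, ",
         length(scores), " scores)")
  pp <- tractogramPaths(t)
  endpointImageFromParts(pp$endpoints, scores, t@grid)
}

endpointImageFromParts <- function(endpoints, scores, grid) {
  arr <- array(0, dim = grid@shape)
  keep <- scores > 0
  lin <- c(endpoints[keep, 1L], endpoints[keep, 2L])
  w <- c(scores[keep], scores[keep])
  ok <- !is.na(lin)
  if (any(ok)) {
    agg <- rowsum(w[ok], lin[ok])
    arr[as.integer(rownames(agg))] <- agg[, 1]
  }
  new("ScalarVolume", grid = grid, data = arr)
}

#' Compute an individual disconnectome map
#'
#' The full chain: score every fiber by its lesion-voxel overlap, project
#' the scores to the fiber endpoints, smooth the endpoint image with a
#' Gaussian kernel, then mask to gray matter. Smoothing precedes masking;
#' endpoints falling outside the GM mask still accumulate in the raw image
#' and are only removed by the final masking step.
#'
#' @param lesion a [BinaryMask-class] of white-matter lesions.
#' @param t a [Tractogram-class] on the same grid.
#' @param gmMask a [BinaryMask-class] of gray matter on the same grid.
#' @param fwhm smoothing kernel FWHM in mm (default 8).
#' @return A [DisconnectomeMap-class].
#' @export
disconnectomeMap <- function(lesion, t, gmMask, fwhm = 8) {
  checkSameGrid(t@grid, lesion@grid, "tractogram and lesion mask")
  checkSameGrid(t@grid, gmMask@grid, "tractogram and GM mask")
  pp <- tractogramPaths(t)
  scores <- scoresFromPaths(pp$paths, lesion)
  raw <- endpointImageFromParts(pp$endpoints, scores, t@grid)
  out <- applyMask(gaussianSmooth(raw, fwhm), gmMask)
  new("DisconnectomeMap", grid = out@grid, data = pmax(out@data, 0),
      fwhm = fwhm, nFibers = nStreamlines(t),
      nLesionVoxels = as.integer(sum(lesion@data)))
}

#' Precompute the per-lesion-voxel disconnectome index
#'
#' For each fiber and each voxel v on its voxel path, records +1 at each of
#' the fiber's two endpoint voxels under key v, aggregated over fibers. For
#' any indexed voxel the total stored contribution is twice the number of
#' fibers whose path contains it. The index stores raw (unsmoothed,
#' unmasked) counts; [fastDisconnectome()] smooths and masks once at query
#' time, which by linearity reproduces [disconnectomeMap()] exactly.
#'
#' @param t a nonempty [Tractogram-class].
#' @return A [VoxelDisconnectomeIndex-class].
#' @export
buildVoxelIndex <- function(t) {
  if (nStreamlines(t) == 0L) stop("tractogram is empty")
  pp <- tractogramPaths(t)
  V <- prod(t@grid@shape)
  ii <- jj <- vector("list", nStreamlines(t))
  for (f in seq_along(pp$paths)) {
    ends <- pp$endpoints[f, ]
    ends <- ends[!is.na(ends)]
    p <- pp$paths[[f]]
    if (length(p) == 0L || length(ends) == 0L) next
    ii[[f]] <- rep(ends, times = length(p))
    jj[[f]] <- rep(p, each = length(ends))
  }
  contrib <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                  x = 1, dims = c(V, V))
  new("VoxelDisconnectomeIndex", grid = t@grid, contrib = contrib,
      nFibers = nStreamlines(t))
}

#' Disconnectome from the precomputed index
#'
#' Sums the stored sparse endpoint contributions over all lesion voxels,
#' then smooths and masks once. Lesion voxels absent from the index simply
#' contribute nothing (no fiber passes through them). Equals
#' [disconnectomeMap()] on the same inputs.
#'
#' @param lesion a [BinaryMask-class].
#' @param idx a [VoxelDisconnectomeIndex-class] on the same grid.
#' @param gmMask a [BinaryMask-class] on the same grid.
#' @param fwhm smoothing kernel FWHM in mm (default 8).
#' @return A [DisconnectomeMap-class].
#' @export
fastDisconnectome <- function(lesion, idx, gmMask, fwhm = 8) {
  checkSameGrid(idx@grid, lesion@grid, "index and lesion mask")
  checkSameGrid(idx@grid, gmMask@grid, "index and GM mask")
  lin <- which(lesion@data != 0)
  raw <- rawEndpointVector(idx, lin)
  vol <- new("ScalarVolume", grid = idx@grid,
             data = array(raw, dim = idx@grid@shape))
  out <- applyMask(gaussianSmooth(vol, fwhm), gmMask)
  new("DisconnectomeMap", grid = out@grid, data = pmax(out@data, 0),
      fwhm = fwhm, nFibers = idx@nFibers,
      nLesionVoxels = as.integer(length(lin)))
}

rawEndpointVector <- function(idx, lesionLinear) {
  if (length(lesionLinear) == 0L) return(numeric(prod(idx@grid@shape)))
  as.numeric(Matrix::rowSums(idx@contrib[, lesionLinear, drop = FALSE]))
}

#' Fiber endpoint density
#'
#' Number of fiber endpoints per voxel: each fiber contributes one count per
#' in-grid endpoint (two when both are inside), so the image total is twice
#' the fiber count minus the number of out-of-grid endpoints. Used to check
#' GM coverage of a connectome template.
#'
#' @param t a nonempty [Tractogram-class].
#' @return A [ScalarVolume-class] of counts.
#' @export
endpointDensity <- function(t) {
  if (nStreamlines(t) == 0L) stop("tractogram is empty")
  pp <- tractogramPaths(t)
  arr <- array(0, dim = t@grid@shape)
  lin <- c(pp$endpoints[, 1L], pp$endpoints[, 2L])
  lin <- lin[!is.na(lin)]
  tab <- rowsum(rep(1, length(lin)), lin)
  arr[as.integer(rownames(tab))] <- tab[, 1]
  new("ScalarVolume", grid = t@grid, data = arr)
}

#' Serialize / load a voxel disconnectome index
#'
#' Container format (version 1): `<prefix>_contrib.mtx`, the sparse
#' endpoint-by-lesion-voxel count matrix in MatrixMarket coordinate format,
#' plus `<prefix>_index.json` holding the format version, the grid (shape,
#' affine) and the fiber count.
#'
#' @param idx a [VoxelDisconnectomeIndex-class].
#' @param prefix file-path prefix.
#' @return `writeVoxelIndex` returns the sidecar path invisibly;
#'   `readVoxelIndex` the reconstructed [VoxelDisconnectomeIndex-class].
#' @export
writeVoxelIndex <- function(idx, prefix) {
  Matrix::writeMM(idx@contrib, paste0(prefix, "_contrib.mtx"))
  side <- paste0(prefix, "_index.json")
  jsonlite::write_json(list(format = "voxel-disconnectome-index",
                            version = 1L,
                            shape = idx@grid@shape,
                            affine = idx@grid@affine,
                            n_fibers = idx@nFibers),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname writeVoxelIndex
#' @export
readVoxelIndex <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_index.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "voxel-disconnectome-index") ||
      meta$version != 1L)
    stop("unrecognized index container at ", prefix)
  grid <- VolumeGrid(meta$shape, affine = matrix(meta$affine, 4L, 4L))
  raw <- Matrix::readMM(paste0(prefix, "_contrib.mtx"))
  # normalize whatever MatrixMarket flavour came back (pattern when all
  # counts are 1, symmetric storage when applicable) to numeric general
  contrib <- methods::as(methods::as(methods::as(raw, "CsparseMatrix"),
                                     "generalMatrix"), "dMatrix")
  new("VoxelDisconnectomeIndex", grid = grid, contrib = contrib,
      nFibers = as.integer(meta$n_fibers))
}
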