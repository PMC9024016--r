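#' @import methods
#' @importFrom stats pt rnorm runif rpois rbinom rlnorm sd p.adjust setNames
#' @importFrom utils read.csv write.csv
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix sparseMatrix
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Volume grid: the shared geometry of all maps
#'
#' A `VolumeGrid` holds the shape (voxels per axis), voxel size (mm) and the
#' 4x4 affine that maps 0-based voxel indices to world millimetre
#' coordinates (`world = affine %*% c(i, j, k, 1)`). Every volume, mask and
#' tractogram in an analysis must live on one common grid; no implicit
#' resampling is ever performed.
#'
#' @slot shape integer(3), voxels per axis (each >= 1).
#' @slot voxelSize numeric(3), voxel edge length in mm per axis (> 0); must
#'   equal the column norms of the affine's 3x3 block.
#' @slot affine 4x4 numeric matrix, invertible.
#' @export
setClass("VolumeGrid",
  representation(shape = "integer", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be 3 integers >= 1")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive finite numbers")
    if (!all(dim(object@affine) == c(4L, 4L)) || any(!is.finite(object@affine)))
      msg <- c(msg, "affine must be a finite 4x4 matrix")
    else {
      d <- abs(det(object@affine[1:3, 1:3]))
      if (d < 1e-12) msg <- c(msg, "affine must be invertible")
      cn <- sqrt(colSums(object@affine[1:3, 1:3]^2))
      if (any(abs(cn - object@voxelSize) > 1e-6 * pmax(1, object@voxelSize)))
        msg <- c(msg, "voxelSize must match affine column norms (1e-6 relative)")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname VolumeGrid-class
#' @param shape integer(3) voxels per axis.
#' @param voxelSize numeric(3) or scalar voxel size in mm (ignored when
#'   `affine` is supplied; then derived from it).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxelSize` with origin placed so that the grid centre maps
#'   to world (0, 0, 0).
#' @return A `VolumeGrid`.
#' @export
VolumeGrid <- function(shape, voxelSize = 1, affine = NULL) {
  shape <- as.integer(shape)
  if (is.null(affine)) {
    voxelSize <- rep_len(as.numeric(voxelSize), 3L)
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -(shape - 1L) / 2 * voxelSize
  } else {
    affine <- unname(as.matrix(affine))
    voxelSize <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  new("VolumeGrid", shape = shape, voxelSize = voxelSize, affine = affine)
}

#' Scalar volume on a grid
#'
#' @slot grid the [VolumeGrid-class] geometry.
#' @slot data numeric 3D array matching the grid shape; all values finite.
#' @export
setClass("ScalarVolume",
  representation(grid = "VolumeGrid", data = "array"),
  validity = function(object) {
    if (!identical(dim(object@data), as.integer(object@grid@shape)))
      return("data dimensions must equal grid shape")
    if (any(!is.finite(object@data))) return("data must be finite everywhere")
    TRUE
  })

#' @rdname ScalarVolume-class
#' @param data numeric array (or value recyclable to the grid shape).
#' @param grid a [VolumeGrid-class].
#' @return A `ScalarVolume`.
#' @export
ScalarVolume <- function(data, grid) {
  data <- array(as.numeric(data), dim = grid@shape)
  new("ScalarVolume", grid = grid, data = data)
}

#' Binary mask on a grid
#'
#' @slot grid the [VolumeGrid-class] geometry.
#' @slot data numeric 3D array of 0/1 values matching the grid shape.
#' @export
setClass("BinaryMask",
  representation(grid = "VolumeGrid", data = "array"),
  validity = function(object) {
    if (!identical(dim(object@data), as.integer(object@grid@shape)))
      return("data dimensions must equal grid shape")
    if (!all(object@data %in% c(0, 1))) return("mask values must be 0 or 1")
    TRUE
  })

#' @rdname BinaryMask-class
#' @param data array coercible to 0/1 (logical allowed).
#' @param grid a [VolumeGrid-class].
#' @return A `BinaryMask`.
#' @export
BinaryMask <- function(data, grid) {
  data <- array(as.numeric(data != 0), dim = grid@shape)
  new("BinaryMask", grid = grid, data = data)
}

#' Tractogram: streamlines in world coordinates over a reference grid
#'
#' Each streamline is an n x 3 matrix of world-mm points in traversal order;
#' the first and last rows are the anatomical endpoints.
#'
#' @slot streamlines list of numeric matrices (n >= 1 rows, 3 columns).
#' @slot grid reference [VolumeGrid-class].
#' @export
setClass("Tractogram",
  representation(streamlines = "list", grid = "VolumeGrid"),
  validity = function(object) {
    ok <- vapply(object@streamlines, function(s)
      is.matrix(s) && ncol(s) == 3L && nrow(s) >= 1L && all(is.finite(s)),
      logical(1))
    if (!all(ok)) return("each streamline must be a finite n x 3 matrix, n >= 1")
    TRUE
  })

#' @rdname Tractogram-class
#' @param streamlines list of n x 3 numeric matrices (world mm).
#' @param grid reference [VolumeGrid-class].
#' @return A `Tractogram`.
#' @export
Tractogram <- function(streamlines, grid) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; unname(s)
  })
  new("Tractogram", streamlines = streamlines, grid = grid)
}

#' Disconnectome map
#'
#' Smoothed, gray-matter-masked endpoint image of lesion-overlap fiber
#' scores; non-negative everywhere and zero for an empty lesion mask.
#'
#' @slot fwhm smoothing kernel FWHM in mm.
#' @slot nFibers number of streamlines used.
#' @slot nLesionVoxels number of lesion voxels in the input mask.
#' @export
setClass("DisconnectomeMap", contains = "ScalarVolume",
  representation(fwhm = "numeric", nFibers = "integer",
                 nLesionVoxels = "integer"),
  validity = function(object) {
    if (any(object@data < -1e-12)) return("disconnectome values must be >= 0")
    TRUE
  })

#' Sparse per-lesion-voxel disconnectome index
#'
#' For every voxel that any fiber passes through, stores the raw (unsmoothed,
#' unmasked) endpoint-count image a single-voxel lesion there would generate,
#' as a sparse endpoint-voxel x lesion-voxel count matrix. Because every step
#' of the disconnectome computation (scoring, endpoint projection, smoothing,
#' masking) is linear in the lesion indicator, summing these columns over the
#' voxels of any lesion mask and then smoothing and masking once reproduces
#' the direct computation exactly.
#'
#' @slot grid the [VolumeGrid-class] shared with the tractogram.
#' @slot contrib `dgCMatrix`, rows indexed by endpoint voxel (linear, 1-based),
#'   columns by lesion voxel; entries are positive integer counts.
#' @slot nFibers number of streamlines indexed.
#' @export
setClass("VoxelDisconnectomeIndex",
  representation(grid = "VolumeGrid", contrib = "Matrix", nFibers = "integer"))

#' Voxel-wise normative model of gray matter
#'
#' Per-voxel ordinary-least-squares coefficients predicting GM from an
#' intercept and mean-centred age, sex and total intracranial volume, fitted
#' on healthy controls.
#'
#' @slot grid the [VolumeGrid-class].
#' @slot beta numeric array of dim `c(shape, 4)`: intercept, age, sex, TIV
#'   slopes per voxel (covariates centred at `covariateMeans`).
#' @slot covariateMeans named numeric(3): means of age, sex, tiv used for
#'   centring.
#' @slot nControls number of control subjects (>= 5).
#' @export
setClass("NormativeModel",
  representation(grid = "VolumeGrid", beta = "array",
                 covariateMeans = "numeric", nControls = "integer"),
  validity = function(object) {
    if (!identical(dim(object@beta), c(as.integer(object@grid@shape), 4L)))
      return("beta must have dim c(shape, 4)")
    if (object@nControls < 5L) return("need at least 5 controls")
    if (!identical(names(object@covariateMeans), c("age", "sex", "tiv")))
      return("covariateMeans must be named age, sex, tiv")
    TRUE
  })

#' Atrophy map: predicted minus observed gray matter
#'
#' Positive values mean less GM than the normative expectation (tissue loss);
#' negative values (observed above prediction) are retained, not clipped.
#' @export
setClass("AtrophyMap", contains = "ScalarVolume")

#' Voxel-wise correlation result
#'
#' @slot grid the [VolumeGrid-class].
#' @slot r per-voxel Pearson (or partial) correlation, 0 outside the mask.
#' @slot p per-voxel two-sided p value (1 outside the mask).
#' @slot q per-voxel Benjamini-Hochberg adjusted value (1 outside the mask).
#' @slot sig [BinaryMask-class] of voxels with q below the FDR level.
#' @slot analysisMask [BinaryMask-class] of voxels entering the analysis.
#' @slot degenerate array flagging in-mask voxels where x or y had zero
#'   variance (r set to 0, p to 1).
#' @slot n number of subjects.
#' @slot nCovariates number of control variables partialled out (0 = plain).
#' @slot alpha FDR level used for `sig`.
#' @export
setClass("CorrelationResult",
  representation(grid = "VolumeGrid", r = "array", p = "array", q = "array",
                 sig = "BinaryMask", analysisMask = "BinaryMask",
                 degenerate = "array", n = "integer", nCovariates = "integer",
                 alpha = "numeric"),
  validity = function(object) {
    if (max(abs(object@r)) > 1 + 1e-12) return("|r| must be <= 1")
    if (any(object@p <= 0) || any(object@p > 1)) return("p must lie in (0, 1]")
    if (any(object@q < object@p - 1e-12)) return("q must be >= p per voxel")
    if (any(object@sig@data > object@analysisMask@data))
      return("significant voxels must lie inside the analysis mask")
    TRUE
  })

#' Synthetic brain phantom
#'
#' A small standard-space stand-in: an ellipsoidal brain mask containing K
#' disjoint spherical gray-matter regions (the labels), the complementary
#' white matter, and a smooth GM probability template peaking in the regions.
#'
#' @slot grid the [VolumeGrid-class] (default 48^3 at 2 mm isotropic).
#' @slot brainMask,gmMask,wmMask [BinaryMask-class] volumes.
#' @slot gmLabels integer array, 0 outside GM, region label 1..K inside.
#' @slot gmTemplate [ScalarVolume-class] in [0, 1].
#' @slot regionCenters K x 3 matrix of region centres (world mm).
#' @slot regionNames data.frame with columns `label`, `name`.
#' @export
setClass("BrainPhantom",
  representation(grid = "VolumeGrid", brainMask = "BinaryMask",
                 gmMask = "BinaryMask", wmMask = "BinaryMask",
                 gmLabels = "array", gmTemplate = "ScalarVolume",
                 regionCenters = "matrix", regionNames = "data.frame"),
  validity = function(object) {
    if (any(object@gmMask@data * object@wmMask@data != 0))
      return("GM and WM masks must be disjoint")
    if (any((object@gmMask@data + object@wmMask@data) > object@brainMask@data))
      return("GM and WM must lie inside the brain mask")
    counts <- table(object@gmLabels[object@gmLabels > 0])
    if (length(counts) && any(counts < 30))
      return("every GM region must contain at least 30 voxels")
    TRUE
  })
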