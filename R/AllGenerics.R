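#' Accessors
#'
#' `volGrid` returns the [VolumeGrid-class] of an object; `volData` the
#' numeric array of a volume or mask; `streamlines` the list of streamline
#' matrices of a [Tractogram-class]; `nStreamlines` their number.
#'
#' @param x an object of one of the package's classes.
#' @return See each description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volGrid", function(x) standardGeneric("volGrid"))
#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' @rdname accessors
setMethod("volGrid", "ScalarVolume", function(x) x@grid)
#' @rdname accessors
setMethod("volGrid", "BinaryMask", function(x) x@grid)
#' @rdname accessors
setMethod("volGrid", "Tractogram", function(x) x@grid)
#' @rdname accessors
setMethod("volGrid", "VoxelDisconnectomeIndex", function(x) x@grid)
#' @rdname accessors
setMethod("volGrid", "NormativeModel", function(x) x@grid)
#' @rdname accessors
setMethod("volGrid", "CorrelationResult", function(x) x@grid)
#' @rdname accessors
setMethod("volGrid", "BrainPhantom", function(x) x@grid)
#' @rdname accessors
setMethod("volData", "ScalarVolume", function(x) x@data)
#' @rdname accessors
setMethod("volData", "BinaryMask", function(x) x@data)
#' @rdname accessors
setMethod("streamlines", "Tractogram", function(x) x@streamlines)
#' @rdname accessors
setMethod("nStreamlines", "Tractogram", function(x) length(x@streamlines))

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid: %s voxels, %s mm\n",
              paste(object@shape, collapse = " x "),
              paste(signif(object@voxelSize, 4), collapse = " x ")))
})

setMethod("show", "ScalarVolume", function(object) {
  cat(sprintf("%s on %s grid; range [%.4g, %.4g]\n", class(object),
              paste(object@grid@shape, collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask on %s grid; %d voxels set\n",
              paste(object@grid@shape, collapse = "x"), sum(object@data)))
})

setMethod("show", "Tractogram", function(object) {
  np <- vapply(object@streamlines, nrow, integer(1))
  cat(sprintf("Tractogram: %d streamlines (%d points) on %s grid\n",
              length(np), sum(np), paste(object@grid@shape, collapse = "x")))
})

setMethod("show", "DisconnectomeMap", function(object) {
  cat(sprintf(paste0("DisconnectomeMap on %s grid; FWHM %.3g mm, %d fibers, ",
                     "%d lesion voxels; max %.4g\n"),
              paste(object@grid@shape, collapse = "x"), object@fwhm,
              object@nFibers, object@nLesionVoxels, max(object@data)))
})

setMethod("show", "VoxelDisconnectomeIndex", function(object) {
  cat(sprintf(paste0("VoxelDisconnectomeIndex: %d fibers, %d traversed ",
                     "voxels, %d sparse entries\n"), object@nFibers,
              sum(Matrix::colSums(object@contrib) > 0),
              length(object@contrib@x)))
})

setMethod("show", "NormativeModel", function(object) {
  cat(sprintf(paste0("NormativeModel on %s grid; n = %d controls; ",
                     "covariate means age %.3g, sex %.3g, tiv %.4g\n"),
              paste(object@grid@shape, collapse = "x"), object@nControls,
              object@covariateMeans[["age"]], object@covariateMeans[["sex"]],
              object@covariateMeans[["tiv"]]))
})

setMethod("show", "CorrelationResult", function(object) {
  inmask <- sum(object@analysisMask@data)
  cat(sprintf(paste0("CorrelationResult: n = %d subjects, %d control ",
                     "variable(s); %d voxels analysed, %d significant ",
                     "(FDR %.3g)\n"), object@n, object@nCovariates, inmask,
              sum(object@sig@data), object@alpha))
})

setMethod("show", "BrainPhantom", function(object) {
  cat(sprintf(paste0("BrainPhantom on %s grid: %d GM regions (%d GM, %d WM, ",
                     "%d brain voxels)\n"),
              paste(object@grid@shape, collapse = "x"),
              nrow(object@regionNames), sum(object@gmMask@data),
              sum(object@wmMask@data), sum(object@brainMask@data)))
})
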