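#' Read and write volumes as NIfTI-1
#'
#' The grid is taken from the NIfTI sform/qform affine, which maps 0-based
#' voxel indices to world mm. Scalar maps are written as float32, masks as
#' uint8.
#'
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return `readVolume` returns a [ScalarVolume-class]; `readMask` a
#'   [BinaryMask-class] (any nonzero voxel counts as 1).
#' @export
readVolume <- function(file) {
  img <- RNifti::readNifti(file)
  grid <- gridFromNifti(img)
  ScalarVolume(as.array(img), grid)
}

#' @rdname readVolume
#' @export
readMask <- function(file) {
  img <- RNifti::readNifti(file)
  grid <- gridFromNifti(img)
  BinaryMask(as.array(img) != 0, grid)
}

gridFromNifti <- function(img) {
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume, got ", length(d), "D")
  VolumeGrid(d, affine = aff)
}

#' @rdname readVolume
#' @param vol a [ScalarVolume-class] or [BinaryMask-class] to write.
#' @export
writeVolume <- function(vol, file) {
  dtype <- if (is(vol, "BinaryMask")) "uint8" else "float"
  arr <- vol@data
  attr(arr, "pixdim") <- vol@grid@voxelSize  # asNifti needs this up front
  img <- RNifti::asNifti(arr, datatype = dtype)
  aff <- structure(vol@grid@affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, file)
  invisible(file)
}
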