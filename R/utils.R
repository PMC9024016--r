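# deterministic per-component substream seeds derived from one master seed;
# kept below 2^31 - 1 so set.seed() accepts them on all platforms
seedFor <- function(master, stream) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 %% m
  as.integer((s + as.numeric(stream) * 69621 + 1) %% m)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# world-mm coordinate vectors of voxel centres along each axis (diagonal or
# general affine; returns a list of three 3D-broadcastable components plus a
# function giving squared distance to a world point)
gridCoordinates <- function(grid) {
  idx <- lapply(grid@shape, function(n) seq_len(n) - 1)
  A <- grid@affine
  offDiag <- A[1:3, 1:3]
  diag(offDiag) <- 0
  if (any(offDiag != 0)) {
    # general affine: materialize full coordinate arrays
    ii <- array(rep(idx[[1]], times = grid@shape[2] * grid@shape[3]),
                grid@shape)
    jj <- aperm(array(rep(idx[[2]], times = grid@shape[1] * grid@shape[3]),
                      grid@shape[c(2, 1, 3)]), c(2, 1, 3))
    kk <- aperm(array(rep(idx[[3]], times = grid@shape[1] * grid@shape[2]),
                      grid@shape[c(3, 1, 2)]), c(2, 3, 1))
    wx <- A[1, 1] * ii + A[1, 2] * jj + A[1, 3] * kk + A[1, 4]
    wy <- A[2, 1] * ii + A[2, 2] * jj + A[2, 3] * kk + A[2, 4]
    wz <- A[3, 1] * ii + A[3, 2] * jj + A[3, 3] * kk + A[3, 4]
    list(separable = FALSE, wx = wx, wy = wy, wz = wz)
  } else {
    list(separable = TRUE,
         x = A[1, 1] * idx[[1]] + A[1, 4],
         y = A[2, 2] * idx[[2]] + A[2, 4],
         z = A[3, 3] * idx[[3]] + A[3, 4])
  }
}

# squared world distance of every voxel centre to a world point
distSqToPoint <- function(coords, p) {
  if (coords$separable)
    outer(outer((coords$x - p[1])^2, (coords$y - p[2])^2, "+"),
          (coords$z - p[3])^2, "+")
  else
    (coords$wx - p[1])^2 + (coords$wy - p[2])^2 + (coords$wz - p[3])^2
}
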