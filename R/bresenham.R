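#' 3D Bresenham voxel traversal between two voxel indices
#'
#' Classic driving-axis integer Bresenham line in 3D (26-connected): the path
#' starts at `a`, ends at `b`, consecutive voxels differ by at most 1 per
#' axis, every axis is monotone along the path, and the path length is the
#' Chebyshev distance plus one. Corner-touching voxels may be skipped (this
#' is not a supercover line).
#'
#' @param a,b integer voxel triples (0-based; any integers are accepted,
#'   clipping to a grid is the caller's concern).
#' @return An m x 3 integer matrix of voxel indices from `a` to `b`.
#' @export
segmentVoxels <- function(a, b) {
  a <- as.integer(round(a)); b <- as.integer(round(b))
  stopifnot(length(a) == 3L, length(b) == 3L)
  d <- abs(b - a)
  s <- as.integer(sign(b - a))
  n <- max(d)
  out <- matrix(0L, n + 1L, 3L)
  out[1L, ] <- a
  if (n == 0L) return(out)
  drive <- which.max(d)
  oth <- setdiff(1:3, drive)
  p <- 2L * d[oth] - d[drive]
  cur <- a
  for (step in seq_len(n)) {
    cur[drive] <- cur[drive] + s[drive]
    for (k in 1:2) {
      if (p[k] >= 0L) {
        cur[oth[k]] <- cur[oth[k]] + s[oth[k]]
        p[k] <- p[k] - 2L * d[drive]
      }
    }
    p <- p + 2L * d[oth]
    out[step + 1L, ] <- cur
  }
  out
}
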