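#' Voxels traversed by a streamline
#'
#' Maps every point of the streamline to continuous voxel coordinates,
#' rounds each to its nearest voxel (voxel-centre convention), rasterizes
#' each consecutive pair with [segmentVoxels()] and concatenates, then
#' deduplicates keeping the first occurrence, so the result is an ordered
#' set: a fiber looping through a voxel twice contributes it once. Voxels
#' outside the grid are dropped (with a warning when the whole streamline
#' falls outside); pass `dedup = FALSE` to keep traversal multiplicities.
#'
#' @param s an n x 3 matrix of world-mm points (a single streamline).
#' @param grid the reference [VolumeGrid-class].
#' @param dedup deduplicate voxels (default `TRUE`, set semantics).
#' @return An m x 3 integer matrix of 0-based in-grid voxel indices.
#' @export
streamlineVoxelPath <- function(s, grid, dedup = TRUE) {
  s <- asPointMatrix(s)
  vox <- worldToVoxel(s, grid)
  if (!is.matrix(vox)) vox <- matrix(vox, 1L, 3L)
  idx <- floor(vox + 0.5)  # rounding without grid clipping; clip at the end
  storage.mode(idx) <- "integer"
  if (nrow(idx) == 1L) {
    path <- idx
  } else {
    segs <- vector("list", nrow(idx) - 1L)
    for (i in seq_len(nrow(idx) - 1L)) {
      seg <- segmentVoxels(idx[i, ], idx[i + 1L, ])
      segs[[i]] <- if (i > 1L) seg[-1L, , drop = FALSE] else seg
    }
    path <- do.call(rbind, segs)
  }
  if (dedup) {
    lin <- path[, 1] + grid@shape[1] * (path[, 2] + grid@shape[2] * path[, 3])
    path <- path[!duplicated(lin), , drop = FALSE]
  }
  inGrid <- path[, 1] >= 0L & path[, 1] < grid@shape[1] &
            path[, 2] >= 0L & path[, 2] < grid@shape[2] &
            path[, 3] >= 0L & path[, 3] < grid@shape[3]
  if (!any(inGrid)) warning("streamline lies entirely outside the grid")
  path[inGrid, , drop = FALSE]
}

#' Endpoint voxels of a streamline
#'
#' The nearest voxels of the first and last point, in order. A single-point
#' streamline returns its voxel twice; an endpoint outside the field of view
#' is marked by an `NA` row, the other endpoint is still returned.
#'
#' @inheritParams streamlineVoxelPath
#' @return A 2 x 3 integer matrix (0-based), rows first/last endpoint.
#' @export
streamlineEndpointVoxels <- function(s, grid) {
  s <- asPointMatrix(s)
  ends <- s[c(1L, nrow(s)), , drop = FALSE]
  nearestVoxel(worldToVoxel(ends, grid), grid)
}

# linear (1-based) voxel paths and endpoint indices for every fiber; the
# workhorse behind scoring, endpoint images and the sparse index. Clipped
# out-of-grid portions are counted once per tractogram.
tractogramPaths <- function(t) {
  grid <- t@grid
  nClipped <- 0L
  paths <- vector("list", nStreamlines(t))
  ends <- matrix(NA_integer_, nStreamlines(t), 2L)
  for (i in seq_along(t@streamlines)) {
    s <- t@streamlines[[i]]
    p <- withCallingHandlers(
      streamlineVoxelPath(s, grid),
      warning = function(w) {
        nClipped <<- nClipped + 1L
        invokeRestart("muffleWarning")
      })
    paths[[i]] <- voxelLinear(p, grid@shape)
    e <- streamlineEndpointVoxels(s, grid)
    ok <- !is.na(e[, 1])
    ends[i, ok] <- voxelLinear(e[ok, , drop = FALSE], grid@shape)
  }
  if (nClipped > 0L)
    warning(nClipped, " streamline(s) lie entirely outside the grid")
  list(paths = paths, endpoints = ends)
}

#' Plain-text streamline format
#'
#' One streamline per block: a line with the point count `n`, followed by
#' `n` lines of `x y z` world-mm coordinates. Blank lines and `#` comments
#' are ignored on read.
#'
#' @param t a [Tractogram-class].
#' @param file path to the text file.
#' @param grid reference [VolumeGrid-class] to attach on read.
#' @return `readTractogramText` returns a [Tractogram-class];
#'   `writeTractogramText` the file path, invisibly.
#' @export
writeTractogramText <- function(t, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# streamlines v1 (n, then n lines of x y z in world mm)", con)
  for (s in t@streamlines) {
    writeLines(as.character(nrow(s)), con)
    writeLines(apply(format(s, digits = 17, trim = TRUE, scientific = FALSE),
                     1L, paste, collapse = " "), con)
  }
  invisible(file)
}

#' @rdname writeTractogramText
#' @export
readTractogramText <- function(file, grid) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n) || n < 1L) stop("malformed streamline count at line ", i)
    if (i + n > length(lines)) stop("truncated streamline block at line ", i)
    pts <- do.call(rbind, lapply(lines[(i + 1L):(i + n)], function(l)
      as.numeric(strsplit(l, "\\s+")[[1]])))
    if (ncol(pts) != 3L || any(!is.finite(pts)))
      stop("malformed point line in block starting at line ", i)
    out[[length(out) + 1L]] <- pts
    i <- i + n + 1L
  }
  Tractogram(out, grid)
}

#' MRtrix TCK tractogram I/O
#'
#' Reads and writes the MRtrix `.tck` format (Float32LE point triples in
#' world/scanner mm, streamlines separated by a NaN triple, terminated by an
#' Inf triple). TRK files are not supported; convert to TCK or the plain-text
#' format first.
#'
#' @param file path to a `.tck` file.
#' @param grid reference [VolumeGrid-class] to attach on read.
#' @param t a [Tractogram-class] to write.
#' @return `readTck` returns a [Tractogram-class]; `writeTck` the path,
#'   invisibly.
#' @export
readTck <- function(file, grid) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file: ", file)
  offset <- NULL
  dtype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || identical(line, "END")) break
    kv <- strsplit(line, ":\\s*")[[1]]
    if (kv[1] == "file") offset <- as.integer(strsplit(kv[2], "\\s+")[[1]][2])
    if (kv[1] == "datatype") dtype <- kv[2]
  }
  if (is.null(offset)) stop("TCK header lacks a 'file' offset")
  if (dtype != "Float32LE") stop("unsupported TCK datatype: ", dtype)
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(file), size = 4L,
                 endian = "little")
  pts <- matrix(raw, ncol = 3L, byrow = TRUE)
  streams <- list()
  start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (!all(is.finite(pts[r, ]))) {
      if (r > start) streams[[length(streams) + 1L]] <-
          pts[start:(r - 1L), , drop = FALSE]
      if (all(is.infinite(pts[r, ]))) break
      start <- r + 1L
    }
  }
  Tractogram(streams, grid)
}

#' @rdname readTck
#' @export
writeTck <- function(t, file) {
  count <- length(t@streamlines)
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", count))
  # the 'file' line states its own byte offset; fix it iteratively
  offset <- 0L
  repeat {
    fileLine <- sprintf("file: . %d", offset)
    bytes <- sum(nchar(c(hdr, fileLine, "END"), type = "bytes") + 1L)
    if (bytes == offset) break
    offset <- bytes
  }
  con <- file(file, "wb")
  on.exit(close(con))
  writeLines(c(hdr, fileLine, "END"), con)
  for (s in t@streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(file)
}
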