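# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# grid whose world coordinates coincide with 0-based voxel indices
idGrid <- function(n = 16) VolumeGrid(c(n, n, n), affine = diag(4))

# full-scale fixtures (48^3 at 2 mm, ~1000 fibers), shared by the heavier
# tests
fullPhantom <- function() cached("fullPhantom", function() makePhantom(seed = 1))
fullTract <- function() cached("fullTract", function()
  makeTractogram(fullPhantom(), seed = 1))
fullIndex <- function() cached("fullIndex", function()
  buildVoxelIndex(fullTract()))
fullCohort <- function() cached("fullCohort", function()
  simulateCohort(fullPhantom(), fullTract(), longitudinal = TRUE, seed = 1))
nullCohort <- function() cached("nullCohort", function()
  simulateCohort(fullPhantom(), fullTract(), alpha = 0, seed = 1))

# small fixtures (36^3, 4 regions, 60 fibers) for fast pipeline tests
smallPhantom <- function() cached("smallPhantom", function()
  makePhantom(shape = c(36, 36, 36), nRegions = 4, seed = 3))
smallTract <- function() cached("smallTract", function()
  makeTractogram(smallPhantom(), nFibersPerPair = 10, seed = 3))

# independent continuous-line rasterization oracle: round the exact line at
# every driving-axis step, ties resolved toward the traversal direction
bresenhamOracle <- function(a, b) {
  d <- b - a
  n <- max(abs(d))
  if (n == 0) return(matrix(as.integer(a), 1L, 3L))
  m <- t(vapply(0:n, function(k) {
    p <- a + d * k / n
    ifelse(sign(d) < 0, ceiling(p - 0.5), floor(p + 0.5))
  }, numeric(3)))
  storage.mode(m) <- "integer"
  unname(m)
}

# brute-force Benjamini-Hochberg from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in seq(m, 1)) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  q
}

sortedVoxelKeys <- function(path, shape = c(64L, 64L, 64L)) {
  sort(path[, 1] + shape[1] * (path[, 2] + shape[2] * path[, 3]))
}
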