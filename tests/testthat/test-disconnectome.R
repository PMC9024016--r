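test_that("fiber lesion scores count path voxels inside the lesion", {
  gi <- idGrid(16)
  s <- rbind(c(2, 2, 2), c(9, 2, 2))  # axis-aligned, 8 path voxels
  empty <- BinaryMask(array(0, c(16, 16, 16)), gi)
  expect_equal(fiberLesionScore(s, empty), 0L)
  full <- BinaryMask(array(1, c(16, 16, 16)), gi)
  expect_equal(fiberLesionScore(s, full), 8L)

  # two disjoint blobs intersecting the path in 2 and 3 voxels
  blob <- array(0, c(16, 16, 16))
  blob[3:4 + 1, 2 + 1, 2 + 1] <- 1     # voxels (3,2,2),(4,2,2)
  blob[6:8 + 1, 2 + 1, 2 + 1] <- 1     # voxels (6,2,2)..(8,2,2)
  lesion <- BinaryMask(blob, gi)
  path <- streamlineVoxelPath(s, gi)
  brute <- sum(vapply(seq_len(nrow(path)), function(i)
    blob[path[i, 1] + 1, path[i, 2] + 1, path[i, 3] + 1] != 0, logical(1)))
  expect_equal(fiberLesionScore(s, lesion), brute)
  expect_equal(fiberLesionScore(s, lesion), 5L)

  gOther <- VolumeGrid(c(16, 16, 16), 2)
  expect_error(fiberLesionScore(s, BinaryMask(array(0, c(16, 16, 16)),
                                              gOther), gi),
               "identical grid")
})

test_that("endpoint images project scores to both endpoints and conserve
           totals", {
  gi <- idGrid(16)
  one <- Tractogram(list(rbind(c(2, 2, 2), c(9, 9, 9))), gi)
  img <- endpointImage(one, 4)
  expect_equal(img@data[3, 3, 3], 4)
  expect_equal(img@data[10, 10, 10], 4)
  expect_equal(sum(img@data), 8)

  loop <- Tractogram(list(rbind(c(2, 2, 2), c(9, 9, 9), c(2, 2, 2))), gi)
  img2 <- endpointImage(loop, 3)
  expect_equal(img2@data[3, 3, 3], 6)  # coincident endpoints accumulate
  expect_equal(sum(img2@data), 6)

  set.seed(7)
  streams <- lapply(1:10, function(i) matrix(runif(6, 1, 14), 2, 3))
  tt <- Tractogram(streams, gi)
  sc <- sample(0:5, 10, replace = TRUE)
  expect_equal(sum(endpointImage(tt, sc)@data), 2 * sum(sc))
  expect_error(endpointImage(tt, 1:3), "one score per fiber")
})

test_that("the disconnectome chain conserves mass for an interior fiber and
           is linear in fibers", {
  g <- VolumeGrid(c(48, 48, 48), 2)
  # axis-aligned fiber through the volume centre, far from all faces
  s <- voxelToWorld(rbind(c(18, 24, 24), c(30, 24, 24)), g)
  tr <- Tractogram(list(s), g)
  lesion <- array(0, c(48, 48, 48))
  lesion[19:31, 25, 25] <- 1          # covers the whole 13-voxel path
  lesionMask <- BinaryMask(lesion, g)
  allGm <- BinaryMask(array(1, c(48, 48, 48)), g)
  dm <- disconnectomeMap(lesionMask, tr, allGm, fwhm = 8)
  expect_equal(sum(dm@data), 2 * 13, tolerance = 1e-5)

  empty <- BinaryMask(array(0, c(48, 48, 48)), g)
  expect_equal(max(disconnectomeMap(empty, tr, allGm)@data), 0)

  tr2 <- Tractogram(c(streamlines(tr), streamlines(tr)), g)
  dm2 <- disconnectomeMap(lesionMask, tr2, allGm, fwhm = 8)
  expect_equal(dm2@data, 2 * dm@data, tolerance = 1e-12)
})

test_that("the voxel index stores per-lesion-voxel endpoint contributions", {
  gi <- idGrid(16)
  s <- rbind(c(2, 2, 2), c(5, 2, 2))
  tr <- Tractogram(list(s), gi)
  idx <- buildVoxelIndex(tr)
  path <- streamlineVoxelPath(s, gi)
  shape <- c(16L, 16L, 16L)
  lin <- function(v) 1L + v[1] + 16L * (v[2] + 16L * v[3])
  e1 <- lin(c(2, 2, 2)); e2 <- lin(c(5, 2, 2))
  for (i in seq_len(nrow(path))) {
    col <- idx@contrib[, lin(path[i, ])]
    expect_equal(sum(col), 2)
    expect_equal(col[e1], 1)
    expect_equal(col[e2], 1)
  }
  # duplicated fiber doubles every contribution
  idx2 <- buildVoxelIndex(Tractogram(list(s, s), gi))
  expect_equal(as.matrix(idx2@contrib), 2 * as.matrix(idx@contrib))
})

test_that("index totals equal twice the fiber-membership counts", {
  gi <- idGrid(24)
  set.seed(13)
  streams <- lapply(1:30, function(i) matrix(runif(9, 1, 22), 3, 3))
  tr <- Tractogram(streams, gi)
  idx <- buildVoxelIndex(tr)
  membership <- integer(24^3)
  for (s in streams) {
    p <- streamlineVoxelPath(s, gi)
    lin <- 1L + p[, 1] + 24L * (p[, 2] + 24L * p[, 3])
    membership[lin] <- membership[lin] + 1L
  }
  expect_equal(as.numeric(Matrix::colSums(idx@contrib)), 2 * membership)
})

test_that("fast index-based disconnectomes equal the direct computation", {
  gi <- idGrid(24)
  set.seed(19)
  streams <- lapply(1:40, function(i) matrix(runif(9, 1, 22), 3, 3))
  tr <- Tractogram(streams, gi)
  idx <- buildVoxelIndex(tr)
  gm <- BinaryMask(array(runif(24^3) > 0.4, c(24, 24, 24)), gi)
  for (rep in 1:5) {
    lesion <- BinaryMask(array(runif(24^3) > 0.97, c(24, 24, 24)), gi)
    direct <- disconnectomeMap(lesion, tr, gm, fwhm = 6)
    fast <- fastDisconnectome(lesion, idx, gm, fwhm = 6)
    expect_equal(fast@data, direct@data, tolerance = 1e-12)
  }
  # empty lesion and single-voxel lesion against the stored column
  empty <- BinaryMask(array(0, c(24, 24, 24)), gi)
  expect_equal(max(fastDisconnectome(empty, idx, gm)@data), 0)
  vLin <- which(Matrix::colSums(idx@contrib) > 0)[1]
  single <- array(0, c(24, 24, 24)); single[vLin] <- 1
  fs <- fastDisconnectome(BinaryMask(single, gi), idx, gm, fwhm = 6)
  col <- array(as.numeric(idx@contrib[, vLin]), c(24, 24, 24))
  expected <- applyMask(gaussianSmooth(ScalarVolume(col, gi), 6), gm)
  expect_equal(fs@data, pmax(expected@data, 0), tolerance = 1e-12)
})

test_that("raw endpoint images are additive over disjoint lesions and
           monotone in lesion voxels", {
  gi <- idGrid(24)
  set.seed(29)
  streams <- lapply(1:25, function(i) matrix(runif(9, 1, 22), 3, 3))
  tr <- Tractogram(streams, gi)
  l1 <- array(runif(24^3) > 0.97, c(24, 24, 24))
  l2 <- array(runif(24^3) > 0.97, c(24, 24, 24)) & !l1
  rawOf <- function(arr)
    endpointImage(tr, fiberScores(tr, BinaryMask(arr, gi)))@data
  expect_equal(rawOf(l1 | l2), rawOf(l1) + rawOf(l2))
  expect_true(all(rawOf(l1 | l2) >= rawOf(l1)))
})

test_that("fiber order never affects the result", {
  gi <- idGrid(24)
  set.seed(37)
  streams <- lapply(1:20, function(i) matrix(runif(9, 1, 22), 3, 3))
  lesion <- BinaryMask(array(runif(24^3) > 0.97, c(24, 24, 24)), gi)
  gm <- BinaryMask(array(1, c(24, 24, 24)), gi)
  d1 <- disconnectomeMap(lesion, Tractogram(streams, gi), gm)
  d2 <- disconnectomeMap(lesion, Tractogram(rev(streams), gi), gm)
  expect_identical(d1@data, d2@data)
})

test_that("endpoint density counts in-grid endpoints", {
  gi <- idGrid(16)
  one <- Tractogram(list(rbind(c(2, 2, 2), c(9, 9, 9))), gi)
  d <- endpointDensity(one)
  expect_equal(d@data[3, 3, 3], 1)
  expect_equal(d@data[10, 10, 10], 1)
  expect_equal(sum(d@data), 2)

  n <- 6
  shared <- lapply(1:n, function(i) rbind(c(4, 4, 4), c(4 + i, 9, 9)))
  dn <- endpointDensity(Tractogram(shared, gi))
  expect_equal(dn@data[5, 5, 5], n)

  set.seed(43)
  streams <- lapply(1:15, function(i) matrix(runif(6, -3, 18), 2, 3))
  tr <- Tractogram(streams, gi)
  ends <- do.call(rbind, lapply(streams, function(s)
    s[c(1, nrow(s)), , drop = FALSE]))
  nOut <- sum(apply(floor(ends + 0.5), 1, function(v)
    any(v < 0 | v > 15)))
  expect_equal(sum(suppressWarnings(endpointDensity(tr))@data),
               2 * 15 - nOut)
})

test_that("the voxel index survives its MatrixMarket container round
           trip", {
  gi <- idGrid(16)
  set.seed(53)
  tr <- Tractogram(lapply(1:12, function(i) matrix(runif(9, 1, 14), 3, 3)),
                   gi)
  idx <- buildVoxelIndex(tr)
  prefix <- file.path(tempdir(), "vidx")
  writeVoxelIndex(idx, prefix)
  idx2 <- readVoxelIndex(prefix)
  expect_equal(as.matrix(idx2@contrib), as.matrix(idx@contrib))
  expect_identical(idx2@grid@shape, idx@grid@shape)
  expect_equal(idx2@grid@affine, idx@grid@affine, tolerance = 1e-12)
  expect_identical(idx2@nFibers, idx@nFibers)
  lesion <- BinaryMask(array(runif(16^3) > 0.95, c(16, 16, 16)), gi)
  gm <- BinaryMask(array(1, c(16, 16, 16)), gi)
  expect_equal(fastDisconnectome(lesion, idx2, gm)@data,
               fastDisconnectome(lesion, idx, gm)@data, tolerance = 1e-12)
})
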