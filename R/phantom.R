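#' Build a synthetic brain phantom
#'
#' An ellipsoidal brain mask on a small standard-space grid containing
#' `nRegions` disjoint spherical gray-matter regions; white matter is the
#' brain interior outside the GM regions; the GM probability template is
#' the region indicator smoothed with a 6-mm Gaussian and rescaled to peak
#' at 1. Region centres are sampled inside the brain with a minimum
#' pairwise separation, by rejection; deterministic for a given seed.
#'
#' @param shape grid shape (default 48^3 voxels).
#' @param voxelSize voxel edge in mm (default 2, isotropic).
#' @param nRegions number of GM regions K (default 8).
#' @param regionRadius GM sphere radius in mm (default 8).
#' @param brainFrac brain ellipsoid semi-axes as a fraction of the half
#'   field of view (default 0.85).
#' @param seed integer seed.
#' @return A [BrainPhantom-class].
#' @export
makePhantom <- function(shape = c(48, 48, 48), voxelSize = 2, nRegions = 8,
                        regionRadius = 8, brainFrac = 0.85, seed = 1) {
  grid <- VolumeGrid(shape, voxelSize)
  coords <- gridCoordinates(grid)
  semi <- brainFrac * (shape * rep_len(voxelSize, 3)) / 2
  cx <- coords$x; cy <- coords$y; cz <- coords$z
  brain <- outer(outer((cx / semi[1])^2, (cy / semi[2])^2, "+"),
                 (cz / semi[3])^2, "+") <= 1
  centers <- withSeed(seedFor(seed, 11L), {
    placed <- matrix(numeric(0), 0, 3)
    tries <- 0L
    maxR <- semi - regionRadius - 2
    if (any(maxR <= 0)) stop("regions do not fit inside the brain")
    while (nrow(placed) < nRegions) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop("could not place ", nRegions, " disjoint GM regions; ",
             "reduce nRegions or regionRadius")
      cand <- runif(3, -1, 1) * maxR
      insideBrain <- sum((cand / (semi - regionRadius - 2))^2) <= 1
      farEnough <- nrow(placed) == 0 ||
        min(sqrt(rowSums(sweep(placed, 2, cand)^2))) >= 2 * regionRadius + 4
      if (insideBrain && farEnough) placed <- rbind(placed, cand)
    }
    placed
  })
  labels <- array(0L, grid@shape)
  for (k in seq_len(nRegions)) {
    d2 <- distSqToPoint(coords, centers[k, ])
    labels[d2 <= regionRadius^2] <- k
  }
  gm <- labels > 0
  wm <- brain & !gm
  tmplRaw <- gaussianSmooth(ScalarVolume(as.numeric(gm), grid), 6)
  tmpl <- tmplRaw@data / max(tmplRaw@data)
  new("BrainPhantom", grid = grid,
      brainMask = BinaryMask(brain, grid),
      gmMask = BinaryMask(gm, grid),
      wmMask = BinaryMask(wm, grid),
      gmLabels = labels,
      gmTemplate = new("ScalarVolume", grid = grid,
                       data = array(tmpl, grid@shape)),
      regionCenters = centers,
      regionNames = data.frame(label = seq_len(nRegions),
                               name = paste0("region_", seq_len(nRegions))))
}

#' Generate a synthetic tractogram over a phantom
#'
#' For each connected region pair, `nFibersPerPair` noisy polylines from a
#' random voxel of region A to a random voxel of region B: endpoints are
#' voxel centres plus sub-voxel jitter (so each endpoint stays inside its
#' region's voxel), and the path is a quadratic Bezier whose control point
#' is the midpoint plus isotropic Gaussian jitter of `jitterSdMm`.
#'
#' @param phantom a [BrainPhantom-class].
#' @param connectivity 2-column matrix of region label pairs; default all
#'   unordered pairs.
#' @param nFibersPerPair streamlines per pair (default 36).
#' @param jitterSdMm midpoint jitter sd in mm (default 4).
#' @param nPoints points per streamline (default 12).
#' @param seed integer seed.
#' @return A [Tractogram-class] in world mm on the phantom grid.
#' @export
makeTractogram <- function(phantom, connectivity = NULL, nFibersPerPair = 36,
                           jitterSdMm = 4, nPoints = 12, seed = 1) {
  K <- nrow(phantom@regionNames)
  if (is.null(connectivity))
    connectivity <- t(utils::combn(K, 2))
  grid <- phantom@grid
  regionVox <- lapply(seq_len(K), function(k)
    linearVoxel(which(phantom@gmLabels == k), grid@shape))
  tt <- seq(0, 1, length.out = nPoints)
  withSeed(seedFor(seed, 23L), {
    streams <- list()
    for (p in seq_len(nrow(connectivity))) {
      va <- regionVox[[connectivity[p, 1]]]
      vb <- regionVox[[connectivity[p, 2]]]
      for (f in seq_len(nFibersPerPair)) {
        A <- voxelToWorld(va[sample.int(nrow(va), 1), ] +
                            runif(3, -0.49, 0.49), grid)
        B <- voxelToWorld(vb[sample.int(nrow(vb), 1), ] +
                            runif(3, -0.49, 0.49), grid)
        C <- (A + B) / 2 + rnorm(3, 0, jitterSdMm)
        pts <- outer((1 - tt)^2, A) + outer(2 * tt * (1 - tt), C) +
          outer(tt^2, B)
        streams[[length(streams) + 1L]] <- pts
      }
    }
    Tractogram(streams, grid)
  })
}

#' Simulate a white-matter lesion mask
#'
#' A Poisson number of spherical lesions with lognormal radii, centres
#' sampled uniformly over the voxels of the supplied mask, voxelized and
#' clipped to that mask (set `clip = FALSE` to keep full spheres within the
#' grid). Deterministic per seed.
#'
#' @param wmMask [BinaryMask-class] of eligible centre voxels (white matter).
#' @param meanLesions Poisson mean lesion count (default 8).
#' @param radiusMeanLog,radiusSdLog lognormal radius parameters in log-mm
#'   (defaults `log(3)` and 0.4).
#' @param seed integer seed.
#' @param clip clip the union of spheres to `wmMask` (default `TRUE`).
#' @return A [BinaryMask-class].
#' @export
simulateLesions <- function(wmMask, meanLesions = 8, radiusMeanLog = log(3),
                            radiusSdLog = 0.4, seed = 1, clip = TRUE) {
  grid <- wmMask@grid
  coords <- gridCoordinates(grid)
  wmLin <- which(wmMask@data != 0)
  withSeed(seedFor(seed, 37L), {
    n <- rpois(1, meanLesions)
    les <- array(FALSE, grid@shape)
    if (n > 0 && length(wmLin) > 0) {
      centerLin <- wmLin[sample.int(length(wmLin), n, replace = TRUE)]
      radii <- rlnorm(n, radiusMeanLog, radiusSdLog)
      centers <- voxelToWorld(linearVoxel(centerLin, grid@shape), grid)
      if (!is.matrix(centers)) centers <- matrix(centers, 1, 3)
      for (l in seq_len(n))
        les <- les | (distSqToPoint(coords, centers[l, ]) <= radii[l]^2)
    }
    if (clip) les <- les & (wmMask@data != 0)
    BinaryMask(les, grid)
  })
}
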