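# stack a list of ScalarVolumes into an n x V matrix restricted to mask
stackMaps <- function(maps, maskLin) {
  vals <- vapply(maps, function(m) as.vector(m@data)[maskLin],
                 numeric(length(maskLin)))
  if (length(maskLin) == 1L) matrix(vals, ncol = 1L) else t(vals)
}

corStats <- function(X, Y, dfResid, refX = colSums(X^2), refY = colSums(Y^2)) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sx <- colSums(Xc^2)
  sy <- colSums(Yc^2)
  # zero variance up to rounding relative to the data scale (covers
  # constants and voxels exactly explained by a residualized covariate)
  degen <- sx <= 1e-18 * refX | sy <= 1e-18 * refY
  r <- numeric(ncol(X))
  den <- sqrt(sx * sy)
  r[!degen] <- colSums(Xc * Yc)[!degen] / den[!degen]
  r <- pmin(1, pmax(-1, r))
  p <- rep(1, ncol(X))
  tt <- r[!degen] * sqrt(dfResid / pmax(1 - r[!degen]^2, .Machine$double.eps))
  p[!degen] <- 2 * pt(-abs(tt), df = dfResid)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  list(r = r, p = p, degenerate = degen)
}

buildCorrelationResult <- function(grid, maskLin, st, mask, n, nCov, alpha) {
  qrej <- fdrCorrect(st$p, alpha)
  toVol <- function(vals, fill) {
    arr <- array(fill, grid@shape)
    arr[maskLin] <- vals
    arr
  }
  sig <- BinaryMask(toVol(as.numeric(qrej$reject), 0), grid)
  new("CorrelationResult", grid = grid,
      r = toVol(st$r, 0), p = toVol(st$p, 1), q = toVol(qrej$q, 1),
      sig = sig, analysisMask = mask,
      degenerate = toVol(as.numeric(st$degenerate), 0),
      n = as.integer(n), nCovariates = as.integer(nCov), alpha = alpha)
}

#' Voxel-wise Pearson correlation across subjects
#'
#' At every voxel of the analysis mask, the sample Pearson correlation of
#' the paired subject values of `xMaps` and `yMaps`, with a two-sided p
#' value from the t transform on n - 2 degrees of freedom. Voxels where x
#' or y has zero variance across subjects are flagged and get r = 0, p = 1.
#' Benjamini-Hochberg adjustment is applied over the in-mask voxels.
#'
#' @param xMaps,yMaps lists of [ScalarVolume-class], paired by subject.
#' @param mask a [BinaryMask-class] of voxels to analyse.
#' @param alpha FDR level for the significance mask (default 0.05).
#' @return A [CorrelationResult-class].
#' @export
voxelwiseCorrelation <- function(xMaps, yMaps, mask, alpha = 0.05) {
  n <- length(xMaps)
  if (n != length(yMaps)) stop("xMaps and yMaps must be paired (same length)")
  if (n < 4L) stop("need at least 4 subjects")
  grid <- mask@grid
  for (m in c(xMaps, yMaps)) checkSameGrid(grid, m@grid, "maps and mask")
  maskLin <- which(mask@data != 0)
  st <- corStats(stackMaps(xMaps, maskLin), stackMaps(yMaps, maskLin),
                 dfResid = n - 2)
  buildCorrelationResult(grid, maskLin, st, mask, n, 0L, alpha)
}

#' Voxel-wise partial correlation controlling for one covariate
#'
#' Residualizes the subject values of x and y at every voxel on an
#' intercept plus the per-subject covariate (ordinary least squares), then
#' correlates the residuals; p values use n - 3 degrees of freedom. A
#' constant covariate reduces to the plain correlation (with a warning and
#' n - 2 degrees of freedom).
#'
#' @inheritParams voxelwiseCorrelation
#' @param covariate numeric vector, one value per subject (e.g. WM lesion
#'   volume in mL).
#' @return A [CorrelationResult-class].
#' @export
voxelwisePartialCorrelation <- function(xMaps, yMaps, covariate, mask,
                                        alpha = 0.05) {
  n <- length(xMaps)
  if (n != length(yMaps)) stop("xMaps and yMaps must be paired (same length)")
  if (length(covariate) != n) stop("need one covariate value per subject")
  if (n < 5L) stop("need at least 5 subjects")
  grid <- mask@grid
  for (m in c(xMaps, yMaps)) checkSameGrid(grid, m@grid, "maps and mask")
  maskLin <- which(mask@data != 0)
  X <- stackMaps(xMaps, maskLin)
  Y <- stackMaps(yMaps, maskLin)
  if (sd(covariate) == 0) {
    warning("constant covariate; falling back to the plain correlation")
    st <- corStats(X, Y, dfResid = n - 2)
    nCov <- 0L
  } else {
    qrD <- qr(cbind(1, covariate))
    st <- corStats(qr.resid(qrD, X), qr.resid(qrD, Y), dfResid = n - 3,
                   refX = colSums(X^2), refY = colSums(Y^2))
    nCov <- 1L
  }
  buildCorrelationResult(grid, maskLin, st, mask, n, nCov, alpha)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Adjusted values `q_i = min_{j >= i} m p_(j) / j` (capped at 1) over the
#' supplied family; rejection where q is below `alpha`.
#'
#' @param p numeric vector of p values in (0, 1].
#' @param alpha FDR level in (0, 1), default 0.05.
#' @return A list with `q` (adjusted values) and `reject` (logical).
#' @export
fdrCorrect <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), reject = logical(0)))
  if (any(p <= 0 | p > 1)) stop("p values must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q < alpha)
}

#' Per-region maxima of a correlation map
#'
#' For every label of an atlas volume, the significant voxel with the
#' largest absolute correlation; regions without significant voxels are
#' marked not significant (`NA` maximum). Labels missing from the name
#' table are reported as "unknown".
#'
#' @param rMap a [ScalarVolume-class] of correlations.
#' @param sig a [BinaryMask-class] of significant voxels.
#' @param labels integer array (same shape) of region labels, 0 = none.
#' @param names data.frame with columns `label`, `name` (optional).
#' @return A data.frame with columns `label`, `name`, `max_r`, `peak_i`,
#'   `peak_j`, `peak_k` (0-based voxel index) and `n_sig_voxels`.
#' @export
regionMax <- function(rMap, sig, labels, names = NULL) {
  checkSameGrid(rMap@grid, sig@grid, "r map and significance mask")
  if (!identical(dim(labels), as.integer(rMap@grid@shape)))
    stop("label volume shape must match the grid")
  labs <- sort(unique(as.integer(labels[labels > 0])))
  rows <- lapply(labs, function(L) {
    lin <- which(labels == L & sig@data != 0)
    nm <- if (!is.null(names) && L %in% names$label)
      names$name[match(L, names$label)] else "unknown"
    if (length(lin) == 0L)
      return(data.frame(label = L, name = nm, max_r = NA_real_,
                        peak_i = NA_integer_, peak_j = NA_integer_,
                        peak_k = NA_integer_, n_sig_voxels = 0L))
    rv <- rMap@data[lin]
    peak <- lin[which.max(abs(rv))]
    pk <- linearVoxel(peak, rMap@grid@shape)
    data.frame(label = L, name = nm, max_r = rv[which.max(abs(rv))],
               peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
               n_sig_voxels = length(lin))
  })
  do.call(rbind, rows)
}

#' Voxel-wise mean of a collection of maps
#'
#' @param maps nonempty list of [ScalarVolume-class] on one grid.
#' @return A [ScalarVolume-class] of per-voxel arithmetic means.
#' @export
cohortMeanMap <- function(maps) {
  if (length(maps) == 0L) stop("need at least one map")
  grid <- maps[[1]]@grid
  acc <- array(0, grid@shape)
  for (m in maps) {
    checkSameGrid(grid, m@grid, "maps")
    acc <- acc + m@data
  }
  new("ScalarVolume", grid = grid, data = acc / length(maps))
}
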