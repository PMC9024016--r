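#' Default analysis mask
#'
#' Gray-matter voxels where at least a fraction `rule` of the subjects have
#' a nonzero value of the x map (disconnection). Falls back to the full GM
#' mask (with a message) when the rule empties the mask, e.g. in a
#' degenerate longitudinal family with no new lesions.
#'
#' @param xMaps list of subject [ScalarVolume-class] maps.
#' @param gmMask [BinaryMask-class].
#' @param rule minimum fraction of subjects with nonzero values (default
#'   0.9).
#' @return A [BinaryMask-class].
#' @export
defaultAnalysisMask <- function(xMaps, gmMask, rule = 0.9) {
  acc <- array(0, gmMask@grid@shape)
  for (m in xMaps) acc <- acc + (m@data != 0)
  keep <- (acc / length(xMaps) >= rule) & (gmMask@data != 0)
  if (!any(keep)) {
    message("analysis-mask rule left no voxels; falling back to the GM mask")
    keep <- gmMask@data != 0
  }
  BinaryMask(keep, gmMask@grid)
}

#' Cross-sectional disconnection-atrophy analysis
#'
#' Fits the normative model on the controls, computes each patient's
#' timepoint-1 disconnectome (via the precomputed voxel index) and atrophy
#' map, and correlates disconnection with atrophy voxel-wise across
#' patients, plain and controlled for total WM lesion volume, under BH-FDR.
#' A region table of per-region maximum correlations is produced from the
#' phantom/atlas labels.
#'
#' @param ds a `cohortDataset` (from [simulateCohort()] or
#'   [readCohortDataset()]).
#' @param fwhm disconnectome smoothing FWHM in mm (default 8).
#' @param alphaFdr FDR level (default 0.05).
#' @param maskRule analysis-mask rule, see [defaultAnalysisMask()].
#' @param atrophyMode `"absolute"` or `"percent"`, see [atrophyMap()].
#' @param outDir optional directory to write NIfTI/CSV/manifest outputs.
#' @return A list of class `analysisBundle` with elements `model`,
#'   `disconnectomes`, `atrophy`, `correlation`, `correlationControlled`,
#'   `regionTable`, `analysisMask`, `meanAtrophy` and `manifest`.
#' @export
runCrossSectional <- function(ds, fwhm = 8, alphaFdr = 0.05, maskRule = 0.9,
                              atrophyMode = "absolute", outDir = NULL) {
  cv <- ds$covariates[ds$covariates$timepoint == 1L, ]
  ctrl <- cv[cv$group == "control", ]
  pat <- cv[cv$group == "patient", ]
  message(nrow(ctrl), " controls and ", nrow(pat),
          " patients at timepoint 1")
  hasLesion <- seq_len(nrow(pat)) <= length(ds$lesions$t1)
  if (!all(hasLesion))
    message("excluding ", sum(!hasLesion), " patient(s) without lesion mask: ",
            paste(pat$subject_id[!hasLesion], collapse = ", "))
  pat <- pat[hasLesion, ]

  model <- fitNormativeModel(ds$controls, ctrl)
  idx <- buildVoxelIndex(ds$tractogram)
  gmMask <- ds$phantom@gmMask
  disc <- lapply(ds$lesions$t1, fastDisconnectome, idx = idx,
                 gmMask = gmMask, fwhm = fwhm)
  atr <- lapply(seq_len(nrow(pat)), function(i)
    atrophyMap(model, pat[i, ], ds$patients$t1[[i]], mode = atrophyMode))
  amask <- defaultAnalysisMask(disc, gmMask, maskRule)
  message(sum(amask@data), " voxels in the analysis mask")
  corr <- voxelwiseCorrelation(disc, atr, amask, alphaFdr)
  corrCtl <- voxelwisePartialCorrelation(disc, atr, pat$lesion_volume_ml,
                                         amask, alphaFdr)
  regTab <- regionMax(new("ScalarVolume", grid = corr@grid, data = corr@r),
                      corr@sig, ds$phantom@gmLabels, ds$phantom@regionNames)
  bundle <- list(model = model, disconnectomes = disc, atrophy = atr,
                 correlation = corr, correlationControlled = corrCtl,
                 regionTable = regTab, analysisMask = amask,
                 meanAtrophy = cohortMeanMap(atr),
                 manifest = list(analysis = "cross_sectional", fwhm = fwhm,
                                 alpha_fdr = alphaFdr, mask_rule = maskRule,
                                 atrophy_mode = atrophyMode,
                                 n_controls = nrow(ctrl),
                                 n_patients = nrow(pat),
                                 n_mask_voxels = sum(amask@data),
                                 package_version =
                                   as.character(utils::packageVersion(
                                     "lesionDisco"))))
  class(bundle) <- "analysisBundle"
  if (!is.null(outDir)) writeAnalysisBundle(bundle, outDir)
  bundle
}

#' Longitudinal disconnection-increase vs atrophy-increase analysis
#'
#' Computes per-patient new-lesion masks (timepoint 2 minus 1), turns them
#' into disconnection-increase maps via the voxel index, forms
#' atrophy-increase maps (each timepoint's atrophy uses the age at that
#' scan), and correlates the increases voxel-wise, plain and controlled for
#' the volume of new WM lesions.
#'
#' @inheritParams runCrossSectional
#' @param maskRule analysis-mask rule (default 0.5: new-lesion families are
#'   sparser than baseline lesion families, so requiring 90% of subjects to
#'   contribute would empty the mask).
#' @return A list of class `analysisBundle` (see [runCrossSectional()]),
#'   with `disconnectomes` holding the increase maps.
#' @export
runLongitudinal <- function(ds, fwhm = 8, alphaFdr = 0.05, maskRule = 0.5,
                            atrophyMode = "absolute", outDir = NULL) {
  if (!isTRUE(ds$longitudinal))
    stop("dataset has no second timepoint")
  cv1 <- ds$covariates[ds$covariates$timepoint == 1L, ]
  cv2 <- ds$covariates[ds$covariates$timepoint == 2L, ]
  ctrl <- cv1[cv1$group == "control", ]
  pat1 <- cv1[cv1$group == "patient", ]
  have2 <- pat1$subject_id %in% cv2$subject_id
  if (!all(have2))
    message("dropping ", sum(!have2), " patient(s) missing timepoint 2: ",
            paste(pat1$subject_id[!have2], collapse = ", "))
  pat1 <- pat1[have2, ]
  pat2 <- cv2[match(pat1$subject_id, cv2$subject_id), ]
  message(nrow(ctrl), " controls; ", nrow(pat1),
          " patients with both timepoints")

  model <- fitNormativeModel(ds$controls, ctrl)
  idx <- buildVoxelIndex(ds$tractogram)
  gmMask <- ds$phantom@gmMask
  kept <- which(have2)
  newMasks <- lapply(kept, function(i)
    lesionIncrease(ds$lesions$t1[[i]], ds$lesions$t2[[i]]))
  discInc <- lapply(newMasks, fastDisconnectome, idx = idx, gmMask = gmMask,
                    fwhm = fwhm)
  atrInc <- lapply(seq_along(kept), function(j) {
    i <- kept[j]
    a1 <- atrophyMap(model, pat1[j, ], ds$patients$t1[[i]], mode = atrophyMode)
    a2 <- atrophyMap(model, pat2[j, ], ds$patients$t2[[i]], mode = atrophyMode)
    mapIncrease(a1, a2)
  })
  amask <- defaultAnalysisMask(discInc, gmMask, maskRule)
  message(sum(amask@data), " voxels in the analysis mask")
  corr <- voxelwiseCorrelation(discInc, atrInc, amask, alphaFdr)
  newVol <- pat2$new_lesion_volume_ml
  corrCtl <- if (sd(newVol) == 0) {
    message("new-lesion volume is constant; controlled analysis flagged ",
            "as degenerate (plain correlation)")
    suppressWarnings(
      voxelwisePartialCorrelation(discInc, atrInc, newVol, amask, alphaFdr))
  } else {
    voxelwisePartialCorrelation(discInc, atrInc, newVol, amask, alphaFdr)
  }
  regTab <- regionMax(new("ScalarVolume", grid = corr@grid, data = corr@r),
                      corr@sig, ds$phantom@gmLabels, ds$phantom@regionNames)
  bundle <- list(model = model, disconnectomes = discInc, atrophy = atrInc,
                 correlation = corr, correlationControlled = corrCtl,
                 regionTable = regTab, analysisMask = amask,
                 meanAtrophy = cohortMeanMap(atrInc),
                 manifest = list(analysis = "longitudinal", fwhm = fwhm,
                                 alpha_fdr = alphaFdr, mask_rule = maskRule,
                                 atrophy_mode = atrophyMode,
                                 n_controls = nrow(ctrl),
                                 n_patients = nrow(pat1),
                                 n_mask_voxels = sum(amask@data),
                                 package_version =
                                   as.character(utils::packageVersion(
                                     "lesionDisco"))))
  class(bundle) <- "analysisBundle"
  if (!is.null(outDir)) writeAnalysisBundle(bundle, outDir)
  bundle
}

#' @export
print.analysisBundle <- function(x, ...) {
  cat(sprintf("analysisBundle (%s): n = %d patients, %d mask voxels, %d significant\n",
              x$manifest$analysis, x$manifest$n_patients,
              x$manifest$n_mask_voxels, sum(x$correlation@sig@data)))
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' r/p/q/significance volumes (plain and controlled) as NIfTI, the region
#' table as CSV, and a JSON run manifest.
#'
#' @param bundle an `analysisBundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeAnalysisBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump <- function(res, tag) {
    grid <- res@grid
    writeVolume(new("ScalarVolume", grid = grid, data = res@r),
                file.path(dir, paste0(tag, "_r.nii.gz")))
    writeVolume(new("ScalarVolume", grid = grid, data = res@p),
                file.path(dir, paste0(tag, "_p.nii.gz")))
    writeVolume(new("ScalarVolume", grid = grid, data = res@q),
                file.path(dir, paste0(tag, "_q.nii.gz")))
    writeVolume(res@sig, file.path(dir, paste0(tag, "_sig.nii.gz")))
  }
  dump(bundle$correlation, "corr")
  dump(bundle$correlationControlled, "corr_controlled")
  writeVolume(bundle$meanAtrophy, file.path(dir, "mean_atrophy.nii.gz"))
  writeVolume(bundle$analysisMask, file.path(dir, "analysis_mask.nii.gz"))
  write.csv(bundle$regionTable, file.path(dir, "region_table.csv"),
            row.names = FALSE)
  writeNormativeModel(bundle$model, file.path(dir, "normative"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run an analysis from a YAML run configuration
#'
#' The configuration holds `dataset` (a cohort directory), `analysis`
#' (`cross` or `longitudinal`), optional `fwhm`, `alpha_fdr`, `mask_rule`,
#' `atrophy_mode` and `out`. Re-running from the same configuration
#' reproduces the outputs (the analysis is deterministic given the data).
#'
#' @param configFile path to the YAML file.
#' @return The `analysisBundle`, invisibly.
#' @export
runFromConfig <- function(configFile) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for configuration files")
  cfg <- yaml::read_yaml(configFile)
  ds <- readCohortDataset(cfg$dataset)
  fun <- switch(match.arg(cfg$analysis, c("cross", "longitudinal")),
                cross = runCrossSectional, longitudinal = runLongitudinal)
  invisible(fun(ds,
                fwhm = cfg$fwhm %||% 8,
                alphaFdr = cfg$alpha_fdr %||% 0.05,
                maskRule = cfg$mask_rule %||% 0.9,
                atrophyMode = cfg$atrophy_mode %||% "absolute",
                outDir = cfg$out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
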