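#' Simulate a control/patient cohort with known ground truth
#'
#' Controls follow the normative generative model
#' `GM = template + betaAge (age - 40) + betaSex sex + betaTiv (tiv - 1500)
#'  + noise` (effects and noise inside the brain mask only). Patients
#' additionally lose GM in proportion to their true disconnection:
#' `alpha * D / M`, where `D` is the patient's disconnectome computed from
#' their simulated lesion mask with the supplied tractogram and `M` the
#' cohort-wide maximum at timepoint 1, so `alpha` is the GM loss (in GM
#' probability units) at the most disconnected voxel.
#'
#' Lesion burden is overdispersed as in clinical relapsing-remitting MS
#' cohorts, whose lesion-volume sd exceeds the mean: every patient draws a
#' lognormal burden multiplier (sd on the log scale `burdenSdLog`, unit
#' mean) that scales the Poisson means of both the baseline and — in
#' longitudinal mode — the new-lesion process, making lesion loads
#' heavy-tailed and correlated within patient.
#'
#' Noise has two components: a persistent per-subject anatomical deviation
#' and independent per-scan noise of sd `scanNoiseSd`, together summing to
#' variance `noiseSd^2` per scan. Cross-sectionally only the total matters;
#' longitudinally the anatomical component cancels in difference maps, as
#' it does in real repeated-measures morphometry.
#'
#' When `alpha = NULL` (the default) the effect size is calibrated to the
#' noise: alpha is set so that the median across core affected voxels of
#' the between-subject sd of the injected GM loss equals `0.5 * noiseSd`
#' (a design signal-to-noise ratio of 0.5). Pass a number to fix the effect
#' instead; `alpha = 0` gives a null cohort.
#'
#' In longitudinal mode the second timepoint adds new lesions, the
#' corresponding incremental connected-GM loss (same normalization `M`),
#' `followupYears` of ageing and fresh scan noise. Covariates: age ~
#' U(20, 60) years, sex ~ Bernoulli(0.675) (female = 1), TIV ~ N(1500, 120)
#' mL. Identical seeds give bit-identical cohorts.
#'
#' The returned object also carries the ground truth: the injected loss
#' maps' cohort mean, an `affectedSupport` mask (any injected loss) and an
#' `affectedCore` mask (mean injected loss at least 10% of its maximum),
#' used to score recovery; longitudinal mode adds the same for the loss
#' increase.
#'
#' @param phantom a [BrainPhantom-class].
#' @param tract a [Tractogram-class] on the phantom grid.
#' @param nControls number of controls (>= 10, default 60).
#' @param nPatients number of patients (>= 10, default 120).
#' @param alpha GM loss at unit normalized disconnection; `NULL` (default)
#'   calibrates to the noise (see Details), 0 gives a null cohort.
#' @param noiseSd total per-scan voxel noise sd in GM units (default 0.015).
#' @param scanNoiseSd sd of the scan-specific noise component (default
#'   0.006; must be below `noiseSd`).
#' @param betaAge,betaSex,betaTiv generative covariate effects (defaults
#'   -0.003 per year, -0.01, 1e-4 per mL).
#' @param meanLesions,newLesionMean baseline Poisson means for baseline and
#'   new lesions before the burden multiplier (defaults 8 and 4.5, keeping
#'   the new/baseline load ratio of clinical cohorts).
#' @param burdenSdLog log-sd of the per-patient lesion burden multiplier
#'   (default 1.1, lesion-load cv about 1.6).
#' @param fwhm smoothing FWHM in mm used for the true disconnectomes
#'   (default 8).
#' @param longitudinal simulate a second timepoint (default `FALSE`).
#' @param followupYears years between timepoints (default 2).
#' @param seed master integer seed.
#' @return A list of class `cohortDataset`; see Details.
#' @export
simulateCohort <- function(phantom, tract, nControls = 60, nPatients = 120,
                           alpha = NULL, noiseSd = 0.015, scanNoiseSd = 0.006,
                           betaAge = -0.003, betaSex = -0.01, betaTiv = 1e-4,
                           meanLesions = 8, newLesionMean = 4.5,
                           burdenSdLog = 1.1, fwhm = 8,
                           longitudinal = FALSE, followupYears = 2,
                           seed = 1) {
  stopifnot(nControls >= 10, nPatients >= 10, scanNoiseSd < noiseSd)
  grid <- phantom@grid
  checkSameGrid(grid, tract@grid, "phantom and tractogram")
  brain <- phantom@brainMask@data
  tmpl <- phantom@gmTemplate@data
  anatSd <- sqrt(noiseSd^2 - scanNoiseSd^2)
  nTotal <- nControls + nPatients
  covs <- withSeed(seedFor(seed, 101L), data.frame(
    subject_id = sprintf("sub%03d", seq_len(nTotal)),
    age = runif(nTotal, 20, 60),
    sex = rbinom(nTotal, 1, 0.675),
    tiv = rnorm(nTotal, 1500, 120),
    group = rep(c("control", "patient"), c(nControls, nPatients)),
    timepoint = 1L, lesion_volume_ml = NA_real_,
    new_lesion_volume_ml = NA_real_, stringsAsFactors = FALSE))

  voxMl <- prod(grid@voxelSize) / 1000
  idx <- buildVoxelIndex(tract)
  gmMask <- phantom@gmMask

  burden <- withSeed(seedFor(seed, 149L),
                     rlnorm(nPatients, -burdenSdLog^2 / 2, burdenSdLog))
  patSeed <- seedFor(seed, 211L)
  lesions1 <- lapply(seq_len(nPatients), function(i)
    simulateLesions(phantom@wmMask, meanLesions * burden[i],
                    seed = patSeed + i))
  disc1 <- lapply(lesions1, fastDisconnectome, idx = idx, gmMask = gmMask,
                  fwhm = fwhm)
  M <- max(1e-12, max(vapply(disc1, function(d) max(d@data), numeric(1))))
  dnorm1 <- lapply(disc1, function(d) d@data / M)

  meanD <- Reduce(`+`, dnorm1) / nPatients
  support1 <- meanD > 1e-12
  core1 <- if (max(meanD) > 0) meanD >= 0.1 * max(meanD) else support1
  if (is.null(alpha)) {
    coreLin <- which(core1)
    if (length(coreLin) == 0L) stop("no affected voxels to calibrate against")
    Dmat <- vapply(dnorm1, function(d) d[coreLin], numeric(length(coreLin)))
    sds <- apply(Dmat, 1L, sd)
    med <- stats::median(sds[sds > 0])
    if (!is.finite(med) || med <= 0)
      stop("disconnection shows no between-subject variance; cannot calibrate")
    alpha <- 0.5 * noiseSd / med
  }
  trueLoss1 <- lapply(dnorm1, function(d) alpha * d)

  baseGm <- function(row) tmpl + brain * (betaAge * (row$age - 40) +
                                            betaSex * row$sex +
                                            betaTiv * (row$tiv - 1500))
  noiseFor <- function(stream, sdev)
    withSeed(seedFor(seed, stream),
             array(rnorm(prod(grid@shape), 0, sdev), grid@shape) * brain)

  controls <- lapply(seq_len(nControls), function(i)
    new("ScalarVolume", grid = grid,
        data = baseGm(covs[i, ]) + noiseFor(1000L + i, noiseSd)))
  patRows <- nControls + seq_len(nPatients)
  anat <- lapply(seq_len(nPatients), function(i) noiseFor(4000L + i, anatSd))
  patients1 <- lapply(seq_len(nPatients), function(i)
    new("ScalarVolume", grid = grid,
        data = baseGm(covs[patRows[i], ]) - trueLoss1[[i]] + anat[[i]] +
          noiseFor(2000L + i, scanNoiseSd)))
  covs$lesion_volume_ml[patRows] <-
    vapply(lesions1, function(l) sum(l@data), numeric(1)) * voxMl

  meanLoss1 <- alpha * meanD

  ds <- list(phantom = phantom, tractogram = tract, covariates = covs,
             controls = controls,
             patients = list(t1 = patients1), lesions = list(t1 = lesions1),
             truth = list(alpha = alpha, noiseSd = noiseSd,
                          scanNoiseSd = scanNoiseSd,
                          betas = c(age = betaAge, sex = betaSex,
                                    tiv = betaTiv),
                          normalization = M, seed = seed, fwhm = fwhm,
                          meanTrueLoss = meanLoss1,
                          affectedSupport = BinaryMask(support1, grid),
                          affectedCore = BinaryMask(core1, grid)),
             longitudinal = longitudinal)

  if (longitudinal) {
    newSeed <- seedFor(seed, 307L)
    newLes <- lapply(seq_len(nPatients), function(i)
      simulateLesions(phantom@wmMask, newLesionMean * burden[i],
                      seed = newSeed + i))
    lesions2 <- lapply(seq_len(nPatients), function(i)
      BinaryMask(pmax(lesions1[[i]]@data, newLes[[i]]@data), grid))
    disc2 <- lapply(lesions2, fastDisconnectome, idx = idx, gmMask = gmMask,
                    fwhm = fwhm)
    trueLoss2 <- lapply(disc2, function(d) alpha * d@data / M)
    covs2 <- covs[patRows, ]
    covs2$age <- covs2$age + followupYears
    covs2$timepoint <- 2L
    covs2$lesion_volume_ml <-
      vapply(lesions2, function(l) sum(l@data), numeric(1)) * voxMl
    covs2$new_lesion_volume_ml <- vapply(seq_len(nPatients), function(i)
      sum(lesions2[[i]]@data) - sum(lesions1[[i]]@data), numeric(1)) * voxMl
    patients2 <- lapply(seq_len(nPatients), function(i)
      new("ScalarVolume", grid = grid,
          data = baseGm(covs2[i, ]) - trueLoss2[[i]] + anat[[i]] +
            noiseFor(3000L + i, scanNoiseSd)))
    lossInc <- lapply(seq_len(nPatients), function(i)
      trueLoss2[[i]] - trueLoss1[[i]])
    meanInc <- Reduce(`+`, lossInc) / nPatients
    coreInc <- if (max(meanInc) > 0) meanInc >= 0.1 * max(meanInc)
               else meanInc > 1e-12
    ds$patients$t2 <- patients2
    ds$lesions$t2 <- lesions2
    ds$covariates <- rbind(covs, covs2)
    ds$truth$meanTrueLossIncrease <- meanInc
    ds$truth$affectedIncreaseCore <- BinaryMask(coreInc, grid)
    ds$truth$affectedIncreaseSupport <- BinaryMask(meanInc > 1e-12, grid)
  }
  class(ds) <- "cohortDataset"
  ds
}

#' @export
print.cohortDataset <- function(x, ...) {
  cat(sprintf(paste0("cohortDataset: %d controls, %d patients%s on %s grid ",
                     "(alpha = %g, noise sd = %g, seed = %d)\n"),
              length(x$controls), length(x$patients$t1),
              if (x$longitudinal) " x 2 timepoints" else "",
              paste(x$phantom@grid@shape, collapse = "x"),
              x$truth$alpha, x$truth$noiseSd, x$truth$seed))
  invisible(x)
}

#' Write / read a cohort dataset directory
#'
#' Writes per-subject GM volumes (`gm_<id>_t<k>.nii.gz`), patient lesion
#' masks (`lesion_<id>_t<k>.nii.gz`), the phantom volumes, the tractogram in
#' the plain-text format, `covariates.csv` and a `truth.json` manifest with
#' the generative parameters (ground-truth masks are stored as NIfTI).
#'
#' @param ds a `cohortDataset` from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `writeCohortDataset` returns `dir` invisibly;
#'   `readCohortDataset` a `cohortDataset` (without per-voxel truth maps
#'   beyond the stored masks and mean-loss volume).
#' @export
writeCohortDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- ds$phantom
  writeVolume(ph@brainMask, file.path(dir, "brain_mask.nii.gz"))
  writeVolume(ph@gmMask, file.path(dir, "gm_mask.nii.gz"))
  writeVolume(ph@wmMask, file.path(dir, "wm_mask.nii.gz"))
  writeVolume(ph@gmTemplate, file.path(dir, "gm_template.nii.gz"))
  writeVolume(new("ScalarVolume", grid = ph@grid,
                  data = array(as.numeric(ph@gmLabels), ph@grid@shape)),
              file.path(dir, "gm_labels.nii.gz"))
  write.csv(ph@regionNames, file.path(dir, "region_names.csv"),
            row.names = FALSE)
  writeTractogramText(ds$tractogram, file.path(dir, "tractogram.txt"))
  write.csv(ds$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  cv <- ds$covariates[ds$covariates$timepoint == 1L, ]
  ctrlIds <- cv$subject_id[cv$group == "control"]
  patIds <- cv$subject_id[cv$group == "patient"]
  for (i in seq_along(ctrlIds))
    writeVolume(ds$controls[[i]],
                file.path(dir, sprintf("gm_%s_t1.nii.gz", ctrlIds[i])))
  tps <- c("t1", if (ds$longitudinal) "t2")
  for (tp in tps) {
    for (i in seq_along(patIds)) {
      writeVolume(ds$patients[[tp]][[i]],
                  file.path(dir, sprintf("gm_%s_%s.nii.gz", patIds[i], tp)))
      writeVolume(ds$lesions[[tp]][[i]],
                  file.path(dir, sprintf("lesion_%s_%s.nii.gz", patIds[i], tp)))
    }
  }
  writeVolume(new("ScalarVolume", grid = ph@grid,
                  data = ds$truth$meanTrueLoss),
              file.path(dir, "truth_mean_loss.nii.gz"))
  writeVolume(ds$truth$affectedSupport,
              file.path(dir, "truth_affected_support.nii.gz"))
  writeVolume(ds$truth$affectedCore,
              file.path(dir, "truth_affected_core.nii.gz"))
  meta <- ds$truth[c("alpha", "noiseSd", "scanNoiseSd", "normalization",
                     "seed", "fwhm")]
  meta$betas <- as.list(ds$truth$betas)
  meta$longitudinal <- ds$longitudinal
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCohortDataset
#' @export
readCohortDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  brain <- readMask(file.path(dir, "brain_mask.nii.gz"))
  gm <- readMask(file.path(dir, "gm_mask.nii.gz"))
  wm <- readMask(file.path(dir, "wm_mask.nii.gz"))
  tmpl <- readVolume(file.path(dir, "gm_template.nii.gz"))
  labVol <- readVolume(file.path(dir, "gm_labels.nii.gz"))
  labels <- array(as.integer(round(labVol@data)), labVol@grid@shape)
  regionNames <- read.csv(file.path(dir, "region_names.csv"),
                          stringsAsFactors = FALSE)
  K <- nrow(regionNames)
  centers <- t(vapply(seq_len(K), function(k) {
    vox <- linearVoxel(which(labels == k), labVol@grid@shape)
    colMeans(voxelToWorld(vox, labVol@grid))
  }, numeric(3)))
  phantom <- new("BrainPhantom", grid = brain@grid, brainMask = brain,
                 gmMask = gm, wmMask = wm, gmLabels = labels,
                 gmTemplate = tmpl, regionCenters = centers,
                 regionNames = regionNames)
  tract <- readTractogramText(file.path(dir, "tractogram.txt"), brain@grid)
  covs <- readCovariates(file.path(dir, "covariates.csv"))
  cv <- covs[covs$timepoint == 1L, ]
  ctrlIds <- cv$subject_id[cv$group == "control"]
  patIds <- cv$subject_id[cv$group == "patient"]
  controls <- lapply(ctrlIds, function(id)
    readVolume(file.path(dir, sprintf("gm_%s_t1.nii.gz", id))))
  longitudinal <- isTRUE(meta$longitudinal)
  tps <- c("t1", if (longitudinal) "t2")
  patients <- lesions <- list()
  for (tp in tps) {
    patients[[tp]] <- lapply(patIds, function(id)
      readVolume(file.path(dir, sprintf("gm_%s_%s.nii.gz", id, tp))))
    lesions[[tp]] <- lapply(patIds, function(id)
      readMask(file.path(dir, sprintf("lesion_%s_%s.nii.gz", id, tp))))
  }
  truth <- list(alpha = meta$alpha, noiseSd = meta$noiseSd,
                scanNoiseSd = meta$scanNoiseSd,
                betas = unlist(meta$betas), normalization = meta$normalization,
                seed = meta$seed, fwhm = meta$fwhm,
                meanTrueLoss = readVolume(
                  file.path(dir, "truth_mean_loss.nii.gz"))@data,
                affectedSupport = readMask(
                  file.path(dir, "truth_affected_support.nii.gz")),
                affectedCore = readMask(
                  file.path(dir, "truth_affected_core.nii.gz")))
  structure(list(phantom = phantom, tractogram = tract, covariates = covs,
                 controls = controls, patients = patients, lesions = lesions,
                 truth = truth, longitudinal = longitudinal),
            class = "cohortDataset")
}
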