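#' Read a covariate table
#'
#' CSV schema (header):
#' `subject_id,age,sex,tiv,group,timepoint,lesion_volume_ml,new_lesion_volume_ml`.
#' `sex` is coded female = 1, male = 0; `age` in years; `tiv` (total
#' intracranial volume) in mL; `group` is `control` or `patient`;
#' `timepoint` 1 or 2; the lesion-volume columns (mL) may be empty for
#' controls.
#'
#' @param file path to the CSV file.
#' @return A validated `data.frame`.
#' @export
readCovariates <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  validateCovariates(df)
  df
}

validateCovariates <- function(df) {
  need <- c("subject_id", "age", "sex", "tiv", "group", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$age <= 0)) stop("age must be positive")
  if (any(df$tiv <= 0)) stop("tiv must be positive")
  if (!all(df$sex %in% c(0, 1))) stop("sex must be 0 (male) or 1 (female)")
  if (!all(df$group %in% c("control", "patient")))
    stop("group must be 'control' or 'patient'")
  invisible(df)
}

# n x 4 design matrix [1, age - m, sex - m, tiv - m]; errors name the
# collinear column
normativeDesign <- function(cov, means = NULL) {
  if (is.null(means))
    means <- c(age = mean(cov$age), sex = mean(cov$sex), tiv = mean(cov$tiv))
  X <- cbind(1, cov$age - means[["age"]], cov$sex - means[["sex"]],
             cov$tiv - means[["tiv"]])
  colnames(X) <- c("intercept", "age", "sex", "tiv")
  list(X = X, means = means)
}

#' Fit the voxel-wise normative model on controls
#'
#' Ordinary least squares of GM value on an intercept and mean-centred age,
#' sex and TIV, independently at every voxel. Centring only improves
#' conditioning; the stored means make predictions reproducible. Voxels with
#' identical GM across controls get slope 0 and intercept equal to that
#' value (up to floating point); no NaNs are produced.
#'
#' @param gmVolumes list of [ScalarVolume-class], one per control.
#' @param covariates data.frame with at least `age`, `sex`, `tiv`
#'   (see [readCovariates()]), one row per volume, same order.
#' @return A [NormativeModel-class].
#' @export
fitNormativeModel <- function(gmVolumes, covariates) {
  n <- length(gmVolumes)
  if (n != nrow(covariates))
    stop("need one covariate row per GM volume")
  if (n < 5L) stop("need at least 5 controls")
  grid <- gmVolumes[[1]]@grid
  for (v in gmVolumes) checkSameGrid(grid, v@grid, "control GM volumes")
  des <- normativeDesign(covariates)
  qrX <- qr(des$X)
  if (qrX$rank < 4L) {
    bad <- colnames(des$X)[qrX$pivot[(qrX$rank + 1L):4L]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- vapply(gmVolumes, function(v) as.vector(v@data),
              numeric(prod(grid@shape)))
  beta <- qr.coef(qrX, t(Y))           # 4 x V
  new("NormativeModel", grid = grid,
      beta = array(t(beta), dim = c(grid@shape, 4L)),
      covariateMeans = des$means, nControls = as.integer(n))
}

#' Predict an individual GM image from the normative model
#'
#' `beta0 + beta_age (age - mean) + beta_sex (sex - mean) +
#'  beta_tiv (tiv - mean)` per voxel.
#'
#' @param model a [NormativeModel-class].
#' @param row a one-row data.frame (or list) with `age`, `sex`, `tiv`.
#' @return A [ScalarVolume-class].
#' @export
predictGm <- function(model, row) {
  m <- model@covariateMeans
  b <- model@beta
  arr <- b[, , , 1L] +
    b[, , , 2L] * (row$age - m[["age"]]) +
    b[, , , 3L] * (row$sex - m[["sex"]]) +
    b[, , , 4L] * (row$tiv - m[["tiv"]])
  new("ScalarVolume", grid = model@grid, data = array(arr, model@grid@shape))
}

#' Individual atrophy map: predicted minus observed GM
#'
#' Positive where the subject has less GM than the normative expectation.
#' With `mode = "percent"` the difference is expressed in percent of the
#' predicted value (voxels with predicted value below `eps` are set to 0).
#'
#' @param model a [NormativeModel-class].
#' @param row covariates of the subject (see [predictGm()]).
#' @param observed the subject's GM [ScalarVolume-class].
#' @param mode `"absolute"` (default) or `"percent"`.
#' @param eps floor on the predicted value for percent mode.
#' @return An [AtrophyMap-class].
#' @export
atrophyMap <- function(model, row, observed, mode = c("absolute", "percent"),
                       eps = 1e-3) {
  mode <- match.arg(mode)
  checkSameGrid(model@grid, observed@grid, "model and observed volume")
  pred <- predictGm(model, row)
  diff <- pred@data - observed@data
  if (mode == "percent") {
    den <- pred@data
    diff <- ifelse(den > eps, 100 * diff / den, 0)
  }
  new("AtrophyMap", grid = model@grid, data = diff)
}

#' New-lesion mask between two timepoints
#'
#' Voxels lesioned at timepoint 2 but not at timepoint 1 (set difference).
#' Voxels where a lesion disappeared do not produce negative values; their
#' count is reported via a message when positive.
#'
#' @param l1,l2 [BinaryMask-class] at timepoints 1 and 2, same grid.
#' @return A [BinaryMask-class].
#' @export
lesionIncrease <- function(l1, l2) {
  checkSameGrid(l1@grid, l2@grid, "lesion masks")
  inc <- (l2@data == 1) & (l1@data == 0)
  gone <- sum((l1@data == 1) & (l2@data == 0))
  if (gone > 0)
    message(gone, " lesion voxel(s) present at t1 disappeared at t2")
  BinaryMask(inc, l1@grid)
}

#' Signed difference of two maps (timepoint 2 minus timepoint 1)
#'
#' @param m1,m2 [ScalarVolume-class] on the same grid.
#' @return A [ScalarVolume-class] `m2 - m1`, unclipped.
#' @export
mapIncrease <- function(m1, m2) {
  checkSameGrid(m1@grid, m2@grid, "maps")
  new("ScalarVolume", grid = m1@grid, data = m2@data - m1@data)
}

#' Serialize / load a normative model
#'
#' Writes the four coefficient volumes as separate float32 NIfTI files
#' (`<prefix>_beta_intercept.nii.gz` etc.) plus a JSON sidecar
#' (`<prefix>_model.json`) holding the centring means and the number of
#' controls.
#'
#' @param model a [NormativeModel-class].
#' @param prefix file-path prefix.
#' @return `writeNormativeModel` returns the sidecar path invisibly;
#'   `readNormativeModel` the reconstructed [NormativeModel-class].
#' @export
writeNormativeModel <- function(model, prefix) {
  comps <- c("intercept", "age", "sex", "tiv")
  for (k in seq_along(comps)) {
    vol <- new("ScalarVolume", grid = model@grid,
               data = array(model@beta[, , , k], model@grid@shape))
    writeVolume(vol, paste0(prefix, "_beta_", comps[k], ".nii.gz"))
  }
  side <- paste0(prefix, "_model.json")
  jsonlite::write_json(list(covariate_means = as.list(model@covariateMeans),
                            n_controls = model@nControls,
                            components = comps),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname writeNormativeModel
#' @export
readNormativeModel <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_model.json"),
                              simplifyVector = TRUE)
  comps <- meta$components
  vols <- lapply(comps, function(k)
    readVolume(paste0(prefix, "_beta_", k, ".nii.gz")))
  grid <- vols[[1]]@grid
  beta <- array(0, c(grid@shape, 4L))
  for (k in seq_along(comps)) beta[, , , k] <- vols[[k]]@data
  new("NormativeModel", grid = grid, beta = beta,
      covariateMeans = unlist(meta$covariate_means)[c("age", "sex", "tiv")],
      nControls = as.integer(meta$n_controls))
}
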