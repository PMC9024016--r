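makeControls <- function(n, grid, gen, seed = 1) {
  set.seed(seed)
  covs <- data.frame(subject_id = sprintf("c%02d", 1:n),
                     age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
                     tiv = rnorm(n, 1500, 100), group = "control",
                     timepoint = 1L)
  vols <- lapply(1:n, function(i)
    ScalarVolume(gen(covs$age[i], covs$sex[i], covs$tiv[i]), grid))
  list(covs = covs, vols = vols)
}

test_that("noise-free linear control data is recovered exactly", {
  g <- idGrid(6)
  cc <- makeControls(20, g, function(age, sex, tiv)
    array(0.8 - 0.004 * age, c(6, 6, 6)))
  m <- fitNormativeModel(cc$vols, cc$covs)
  expect_equal(max(abs(m@beta[, , , 2] + 0.004)), 0, tolerance = 1e-9)
  expect_equal(max(abs(m@beta[, , , 3])), 0, tolerance = 1e-9)
  expect_equal(max(abs(m@beta[, , , 4])), 0, tolerance = 1e-9)
  # residuals vanish for every control
  for (i in c(1, 10, 20)) {
    pred <- predictGm(m, cc$covs[i, ])
    expect_equal(pred@data, cc$vols[[i]]@data, tolerance = 1e-9)
  }
})

test_that("identical control volumes give zero slopes and that volume as
           intercept", {
  g <- idGrid(5)
  set.seed(2)
  base <- array(runif(125), c(5, 5, 5))
  cc <- makeControls(12, g, function(age, sex, tiv) base)
  m <- fitNormativeModel(cc$vols, cc$covs)
  expect_equal(array(m@beta[, , , 1], c(5, 5, 5)), base, tolerance = 1e-9)
  expect_equal(max(abs(m@beta[, , , 2:4])), 0, tolerance = 1e-9)
})

test_that("noisy betas land within 3 analytic standard errors at almost all
           voxels", {
  g <- idGrid(12)
  sdN <- 0.02
  trueB <- c(0.7, -0.003, -0.01, 1e-4)
  set.seed(3)
  n <- 60
  covs <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
                     tiv = rnorm(n, 1500, 100))
  vols <- lapply(1:n, function(i)
    ScalarVolume(array(trueB[1] + trueB[2] * covs$age[i] +
                         trueB[3] * covs$sex[i] + trueB[4] * covs$tiv[i] +
                         rnorm(12^3, 0, sdN), c(12, 12, 12)), g))
  m <- fitNormativeModel(vols, covs)
  X <- cbind(1, covs$age - mean(covs$age), covs$sex - mean(covs$sex),
             covs$tiv - mean(covs$tiv))
  se <- sdN * sqrt(diag(solve(crossprod(X))))
  # centred-model true coefficients
  trueC <- c(trueB[1] + trueB[2] * mean(covs$age) +
               trueB[3] * mean(covs$sex) + trueB[4] * mean(covs$tiv),
             trueB[2:4])
  for (k in 1:4) {
    frac <- mean(abs(m@beta[, , , k] - trueC[k]) <= 3 * se[k])
    expect_gte(frac, 0.99)
  }
})

test_that("prediction is linear in covariates and centred at the means", {
  g <- idGrid(6)
  set.seed(4)
  cc <- makeControls(15, g, function(age, sex, tiv)
    array(0.9 - 0.002 * age + 0.05 * sex + 2e-5 * tiv + rnorm(216, 0, 0.01),
          c(6, 6, 6)))
  m <- fitNormativeModel(cc$vols, cc$covs)
  atMeans <- predictGm(m, data.frame(age = m@covariateMeans[["age"]],
                                     sex = m@covariateMeans[["sex"]],
                                     tiv = m@covariateMeans[["tiv"]]))
  expect_equal(atMeans@data, array(m@beta[, , , 1], c(6, 6, 6)),
               tolerance = 1e-12)
  r1 <- data.frame(age = 30, sex = 1, tiv = 1450)
  r2 <- data.frame(age = 40, sex = 1, tiv = 1450)
  expect_equal(predictGm(m, r2)@data - predictGm(m, r1)@data,
               array(10 * m@beta[, , , 2], c(6, 6, 6)), tolerance = 1e-12)
})

test_that("per-voxel OLS agrees with lm fitted on uncentred covariates", {
  g <- idGrid(4)
  set.seed(5)
  cc <- makeControls(25, g, function(age, sex, tiv)
    array(rnorm(64, 0.8, 0.05), c(4, 4, 4)))
  m <- fitNormativeModel(cc$vols, cc$covs)
  y <- vapply(cc$vols, function(v) v@data[2, 3, 1], numeric(1))
  fit <- lm(y ~ age + sex + tiv, data = cc$covs)
  newRow <- data.frame(age = 33, sex = 0, tiv = 1520)
  expect_equal(predictGm(m, newRow)@data[2, 3, 1],
               unname(predict(fit, newRow)), tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear column named", {
  g <- idGrid(4)
  set.seed(6)
  cc <- makeControls(10, g, function(age, sex, tiv)
    array(runif(64), c(4, 4, 4)))
  cc$covs$sex <- 1  # single-sex cohort
  expect_error(fitNormativeModel(cc$vols, cc$covs), "sex")
})

test_that("atrophy is predicted minus observed, with shift equivariance and
           a percent mode", {
  g <- idGrid(6)
  set.seed(7)
  cc <- makeControls(15, g, function(age, sex, tiv)
    array(0.8 - 0.002 * age + rnorm(216, 0, 0.01), c(6, 6, 6)))
  m <- fitNormativeModel(cc$vols, cc$covs)
  row <- data.frame(age = 45, sex = 1, tiv = 1500)
  pred <- predictGm(m, row)
  expect_equal(max(abs(atrophyMap(m, row, pred)@data)), 0)
  shifted <- ScalarVolume(pred@data - 0.05, g)
  expect_equal(atrophyMap(m, row, shifted)@data,
               array(0.05, c(6, 6, 6)), tolerance = 1e-12)
  # adding c to the observed volume lowers atrophy by exactly c
  obs <- ScalarVolume(pred@data + array(rnorm(216, 0, 0.02), c(6, 6, 6)), g)
  a0 <- atrophyMap(m, row, obs)
  a1 <- atrophyMap(m, row, ScalarVolume(obs@data + 0.03, g))
  expect_equal(a1@data, a0@data - 0.03, tolerance = 1e-12)
  pc <- atrophyMap(m, row, shifted, mode = "percent")
  expect_equal(pc@data, 100 * 0.05 / pred@data, tolerance = 1e-12)
})

test_that("mean atrophy recovers an injected loss field across subjects", {
  g <- idGrid(8)
  sdN <- 0.02
  set.seed(8)
  cc <- makeControls(40, g, function(age, sex, tiv)
    array(0.8 - 0.002 * age + rnorm(512, 0, sdN), c(8, 8, 8)))
  m <- fitNormativeModel(cc$vols, cc$covs)
  delta <- array(runif(512, 0, 0.06), c(8, 8, 8))
  nPat <- 50
  set.seed(9)
  atros <- lapply(1:nPat, function(i) {
    row <- data.frame(age = runif(1, 20, 60), sex = rbinom(1, 1, 0.5),
                      tiv = rnorm(1, 1500, 100))
    obs <- ScalarVolume(0.8 - 0.002 * row$age - delta +
                          array(rnorm(512, 0, sdN), c(8, 8, 8)), g)
    atrophyMap(m, row, obs)@data
  })
  meanAtr <- Reduce(`+`, atros) / nPat
  # within 2 sd/sqrt(n) allowing for model-estimation error
  tol <- 2 * sdN / sqrt(nPat) * 1.5
  expect_gt(mean(abs(meanAtr - delta) <= tol), 0.93)
  expect_lt(max(abs(meanAtr - delta)), 6 * sdN / sqrt(nPat))
})

test_that("lesion increase is a set difference and map increase is signed", {
  g <- idGrid(8)
  set.seed(10)
  l1 <- BinaryMask(array(runif(512) > 0.8, c(8, 8, 8)), g)
  expect_equal(sum(lesionIncrease(l1, l1)@data), 0)
  empty <- BinaryMask(array(0, c(8, 8, 8)), g)
  expect_equal(lesionIncrease(empty, l1)@data, l1@data)
  # shrinking lesion: increase empty, disappearing voxels reported
  sub <- BinaryMask(l1@data * (array(runif(512), c(8, 8, 8)) > 0.5), g)
  expect_message(inc <- lesionIncrease(l1, sub), "disappeared")
  expect_equal(sum(inc@data), 0)

  m1 <- ScalarVolume(array(rnorm(512), c(8, 8, 8)), g)
  m2 <- ScalarVolume(array(rnorm(512), c(8, 8, 8)), g)
  expect_equal(mapIncrease(m1, m2)@data, -mapIncrease(m2, m1)@data)
  expect_equal(mapIncrease(m1, ScalarVolume(m1@data + 0.2, g))@data,
               array(0.2, c(8, 8, 8)), tolerance = 1e-12)
})

test_that("the normative model survives NIfTI + sidecar serialization", {
  g <- idGrid(6)
  set.seed(11)
  cc <- makeControls(15, g, function(age, sex, tiv)
    array(0.8 - 0.002 * age + 0.03 * sex + rnorm(216, 0, 0.01), c(6, 6, 6)))
  m <- fitNormativeModel(cc$vols, cc$covs)
  prefix <- file.path(tempdir(), "nm")
  writeNormativeModel(m, prefix)
  m2 <- readNormativeModel(prefix)
  expect_equal(m2@beta, m@beta, tolerance = 1e-5)  # float32 storage
  expect_equal(m2@covariateMeans, m@covariateMeans, tolerance = 1e-12)
  expect_equal(m2@nControls, m@nControls)
  row <- data.frame(age = 50, sex = 0, tiv = 1600)
  expect_equal(predictGm(m2, row)@data, predictGm(m, row)@data,
               tolerance = 1e-4)
})

test_that("covariate tables are validated against the schema", {
  df <- data.frame(subject_id = "s1", age = 30, sex = 1, tiv = 1500,
                   group = "control", timepoint = 1L)
  expect_silent(validOk <- lesionDisco::readCovariates(
    { f <- tempfile(fileext = ".csv"); write.csv(df, f, row.names = FALSE); f }))
  bad <- df; bad$sex <- 2
  f2 <- tempfile(fileext = ".csv"); write.csv(bad, f2, row.names = FALSE)
  expect_error(readCovariates(f2), "sex")
  bad2 <- df; bad2$age <- -1
  f3 <- tempfile(fileext = ".csv"); write.csv(bad2, f3, row.names = FALSE)
  expect_error(readCovariates(f3), "age")
})
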