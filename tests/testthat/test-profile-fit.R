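calcGauss <- function(q = seq(0.01, 0.3, length.out = 200))
  ScatteringProfile(q, 100 * exp(-q^2 * 75))

test_that("closed-form scale recovery and zero chi2 on self-fits", {
  calc <- calcGauss()
  expd <- ScatteringProfile(qValues(calc), intensities(calc),
                            sigma = rep(1, 200))
  fr <- fitScale(calc, expd)
  expect_equal(scaleFactor(fr), 1, tolerance = 1e-12)
  expect_equal(chiSquare(fr), 0, tolerance = 1e-20)
  ## multiplicative rescaling of the model is absorbed entirely
  ex3 <- ScatteringProfile(qValues(calc), 3 * intensities(calc),
                           sigma = rep(1, 200))
  fr3 <- fitScale(calc, ex3)
  expect_equal(scaleFactor(fr3), 3, tolerance = 1e-12)
  expect_equal(chiSquare(fr3), 0, tolerance = 1e-18)
})

test_that("reduced chi2 of self-fit with unit-sigma noise is ~1", {
  calc <- calcGauss()
  set.seed(11)
  chis <- vapply(1:50, function(i) {
    Ie <- intensities(calc) + rnorm(200)
    chiSquare(fitScale(calc, ScatteringProfile(qValues(calc), Ie,
                                               sigma = rep(1, 200))))
  }, numeric(1))
  expect_equal(mean(chis), 1.0, tolerance = 0.1)
})

test_that("chi2 is invariant under common rescaling of (I, sigma)", {
  calc <- calcGauss()
  set.seed(4)
  Ie <- intensities(calc) + rnorm(200, 0, 0.5)
  e1 <- ScatteringProfile(qValues(calc), Ie, sigma = rep(0.5, 200))
  e2 <- ScatteringProfile(qValues(calc), 10 * Ie, sigma = rep(5, 200))
  expect_equal(chiSquare(fitScale(calc, e1)), chiSquare(fitScale(calc, e2)),
               tolerance = 1e-10)
})

test_that("flat-background pitfall: offset data punished unless background is fitted", {
  calc <- calcGauss()
  set.seed(5)
  Ie <- intensities(calc) + rnorm(200, 0, 0.5)
  base <- ScatteringProfile(qValues(calc), Ie, sigma = rep(0.5, 200))
  offs <- ScatteringProfile(qValues(calc), Ie + 3, sigma = rep(0.5, 200))
  expect_gt(chiSquare(fitScale(calc, offs)), chiSquare(fitScale(calc, base)))
  frB <- fitScale(calc, offs, fitBackground = TRUE)
  expect_equal(frB@background, 3, tolerance = 0.1)
  expect_lt(chiSquare(frB), chiSquare(fitScale(calc, offs)))
})

test_that("interpolation onto the experimental grid is accurate and bounded", {
  qf <- seq(0.01, 0.3, length.out = 2000)
  calc <- ScatteringProfile(qf, 100 * exp(-qf^2 * 75))
  qe <- seq(0.012, 0.29, length.out = 73)
  expd <- ScatteringProfile(qe, 100 * exp(-qe^2 * 75),
                            sigma = rep(0.01, 73))
  fr <- fitScale(calc, expd)
  expect_lt(max(abs(fr@residuals * 0.01 / (100 * exp(-qe^2 * 75)))), 0.001)
  ## no overlap -> error; missing sigma -> loud failure
  far <- ScatteringProfile(qe + 10, intensities(expd), sigma = rep(1, 73))
  expect_error(fitScale(calc, far), "overlap")
  nos <- ScatteringProfile(qe, intensities(expd))
  expect_error(fitScale(calc, nos), "no uncertainties")
})

test_that("model ranking is stable, ordered and failure-tolerant", {
  calc <- calcGauss()
  set.seed(8)
  Ie <- intensities(calc) + rnorm(200, 0, 0.5)
  expd <- ScatteringProfile(qValues(calc), Ie, sigma = rep(0.5, 200))
  perturbed <- ScatteringProfile(qValues(calc),
                                 intensities(calc) * (1 + 0.2 * qValues(calc) / 0.3))
  tab1 <- rankModels(list(good = calc), expd)
  expect_equal(nrow(tab1), 1)
  tab <- rankModels(list(perturbed = perturbed, good = calc), expd)
  expect_equal(tab$model[1], "good")
  expect_equal(tab$deltaChi2[1], 0)
  expect_gt(tab$deltaChi2[2], 0)
  ## rigid rotation of a model leaves the profile, hence chi2, unchanged
  set.seed(13)
  xyz <- matrix(rnorm(50 * 3, sd = 8), ncol = 3)
  rot <- xyz %*% matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mk <- function(m) {
    df <- data.frame(element = "BEAD", x = m[, 1], y = m[, 2], z = m[, 3],
                     resid = "BEA", resno = 1:50, chain = "A",
                     hNonexch = 0, hExch = 0, volume = 280)
    unitProfile(atomicModel(df, c(A = 0)), qValues(calc))
  }
  pa <- mk(xyz); pb <- mk(rot)
  expd2 <- ScatteringProfile(qValues(calc), intensities(pa),
                             sigma = rep(1, 200))
  tabR <- rankModels(list(first = pa, second = pb), expd2)
  expect_equal(tabR$chi2[1], tabR$chi2[2], tolerance = 1e-9)
  expect_equal(tabR$model, c("first", "second"))  # stable tie order
  ## a failing candidate is flagged, not fatal
  bad <- ScatteringProfile(qValues(calc) + 10, intensities(calc))
  tabF <- rankModels(list(good = calc, bad = bad), expd)
  expect_true(tabF$ok[1]); expect_false(tabF$ok[2])
})
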