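test_that("Guinier fit recovers exact generating parameters", {
  p <- gaussianProfile(Rg = 15, I0 = 100)
  g <- guinierFit(p)
  expect_equal(rgValue(g), 15, tolerance = 1e-6)
  expect_equal(i0Value(g), 100, tolerance = 1e-6)
  expect_lte(g@qRgMax, 1.3 + 1e-9)
  ## weighted path with constant sigma gives the same answer
  pw <- ScatteringProfile(qValues(p), intensities(p),
                          sigma = rep(1, length(p)))
  expect_equal(rgValue(guinierFit(pw)), 15, tolerance = 1e-4)
})

test_that("Guinier fit on a noiseless sphere matches sqrt(3/5) R", {
  p <- sphereProfile(R = 20, qmin = 0.005, dq = 0.0025)
  g <- guinierFit(p)
  expect_equal(rgValue(g), sqrt(3 / 5) * 20, tolerance = 0.1 / 15.49)
})

test_that("Guinier failure modes are loud", {
  q <- seq(0.01, 0.1, 0.01)
  expect_error(guinierFit(ScatteringProfile(q, rep(-1, 10))),
               "no Guinier region")
  ## rising intensity: no negative slope anywhere
  expect_error(guinierFit(ScatteringProfile(q, exp(q^2 * 300))),
               "no Guinier region")
  ## fixed window works and respects bounds
  p <- gaussianProfile()
  g <- guinierFit(p, window = c(0.01, 0.05))
  expect_gte(g@qmin, 0.01); expect_lte(g@qmax, 0.05)
})

test_that("dimensionless Kratky: Gaussian peak at (sqrt(3), 3/e); origin flatness", {
  p <- gaussianProfile(Rg = 15, I0 = 50, dq = 0.001)
  g <- guinierFit(p)
  k <- dimensionlessKratky(p, g)
  pk <- attr(k, "peak")
  expect_equal(pk$y, 3 / exp(1), tolerance = 1e-3)
  expect_equal(pk$qRg, sqrt(3), tolerance = 0.01)
  ## curve passes through the origin with zero slope: near q = 0 the
  ## ordinate is quadratic, so y/qRg is itself of order qRg
  expect_lt(k$y[1], 0.01)
  expect_lt(k$y[1] / k$qRg[1], 2 * k$qRg[1])
  ## sigma propagation
  ps <- ScatteringProfile(qValues(p), intensities(p),
                          sigma = rep(0.5, length(p)))
  ks <- dimensionlessKratky(ps, g)
  expect_equal(ks$sigmaY, ks$qRg^2 * 0.5 / i0Value(g), tolerance = 1e-12)
})

test_that("dimensionless Kratky: sphere near the globular guideline, rod above it", {
  ps <- sphereProfile(R = 20, dq = 0.002)
  gs <- guinierFit(ps)
  pk <- attr(dimensionlessKratky(ps, gs), "peak")
  expect_equal(pk$y, 1.1, tolerance = 0.1)
  expect_gt(pk$qRg, 1.4); expect_lt(pk$qRg, 2.0)
  rod <- generateShape("rod", length = 100, diameter = 20, n = 1200,
                       seed = 9)
  q <- seq(0.006, 0.35, 0.003)
  pr <- unitProfile(rod, q)
  gr <- guinierFit(pr, qRgMax = 1.0)
  kr <- dimensionlessKratky(pr, gr)
  pkr <- attr(kr, "peak")
  expect_gt(pkr$y, 1.1)
  ## declines slowly: still well above zero far beyond the peak
  expect_gt(kr$y[which.min(abs(kr$qRg - 4))], 0.5 * pkr$y)
})

test_that("Porod volume: convergence to sphere volume, scale invariance, I0 monotonicity", {
  q <- seq(0.004, 1.0, 0.002)
  p <- ScatteringProfile(q, sphereFF(q, 20))
  g <- guinierFit(p)
  vtrue <- 4 / 3 * pi * 20^3
  pm <- porodMW(p, g, qCutoff = 0.8)
  expect_equal(pm$vp, vtrue, tolerance = 0.1)
  expect_equal(pm$mw, pm$vp * 0.00054, tolerance = 1e-12)
  ## truncation at small cutoff*Rg overestimates the volume (documented)
  expect_gt(porodMW(p, g, qCutoff = 0.15)$vp, pm$vp)
  ## scale invariance: I -> c I leaves Vp unchanged
  p7 <- ScatteringProfile(q, 7 * sphereFF(q, 20))
  expect_equal(porodMW(p7, guinierFit(p7), qCutoff = 0.8)$vp, pm$vp,
               tolerance = 1e-6)
  ## monotone in I0 at fixed Q
  gUp <- new("GuinierResult", rg = g@rg, rgErr = g@rgErr, i0 = 2 * g@i0,
             i0Err = g@i0Err, qmin = g@qmin, qmax = g@qmax,
             qRgMax = g@qRgMax, r2 = g@r2, nPoints = g@nPoints)
  ## same Q would require same integrand; compare Vp = 2 pi^2 I0 / Q directly
  expect_gt(2 * pi^2 * gUp@i0 / pm$Q, pm$vp)
  ## cutoff beyond the data is refused with the achievable cutoff named
  pshort <- ScatteringProfile(q[q <= 0.1], sphereFF(q[q <= 0.1], 20))
  expect_error(porodMW(pshort, g), "achievable cutoff")
})

test_that("logarithmic rebinning: counts, weighted means, propagation", {
  q <- exp(seq(log(0.001), log(1), length.out = 1200))
  p <- ScatteringProfile(q, rep(5, 1200), sigma = rep(0.2, 1200))
  rb <- logRebin(p, 33)
  ## 3 decades -> ~99 bins (minus boundary effects)
  expect_gte(length(rb), 95); expect_lte(length(rb), 100)
  expect_equal(intensities(rb), rep(5, length(rb)), tolerance = 1e-12)
  ## sigma shrinks as 1/sqrt(occupancy)
  occ <- tabulate(findInterval(q, 10^seq(-3 - 1e-9, 0 + 1e-9, by = 1 / 33),
                               rightmost.closed = TRUE))
  expect_true(all(sigmas(rb) <= 0.2 + 1e-12))
  expect_lt(min(sigmas(rb)), 0.2 / sqrt(max(occ) / 2))
  ## rebin(66) then Guinier agrees with the un-rebinned fit
  pg <- ScatteringProfile(seq(0.002, 0.2, length.out = 1500),
                          100 * exp(-seq(0.002, 0.2, length.out = 1500)^2 *
                                    225 / 3),
                          sigma = rep(0.1, 1500))
  rg1 <- rgValue(guinierFit(pg))
  rg2 <- rgValue(guinierFit(logRebin(pg, 66)))
  expect_equal(rg2, rg1, tolerance = 0.01)
  expect_error(logRebin(p, 0), ">= 1")
})
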