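test_that("shape generators honour their geometry", {
  sph <- generateShape("sphere", R = 20, n = 3000, seed = 7)
  expect_equal(nParticles(sph), 3000)
  expect_equal(coordinateRg(sph), sqrt(3 / 5) * 20, tolerance = 0.3 / 15.49)
  ## all beads inside the ball
  xyz <- as.matrix(particles(sph)[, c("x", "y", "z")])
  expect_true(all(rowSums(xyz^2) <= 20^2 + 1e-9))
  h <- generateShape("helix", nBp = 16)
  expect_equal(diff(range(particles(h)$z)), 16 * 2.8, tolerance = 2 / 44.8)
  ## radial extent follows the diameter parameter
  expect_equal(max(sqrt(particles(h)$x^2 + particles(h)$y^2)), 10,
               tolerance = 1e-9)
  cm <- generateShape("two_hairpin_complex", nBpA = 12, nBpB = 28,
                      chainD = c(A = 0, B = 1))
  expect_setequal(unique(particles(cm)$chain), c("A", "B"))
  expect_equal(unname(chainLabels(cm)["B"]), 1)
  expect_error(generateShape("sphere", R = -1, n = 10, seed = 1),
               "invalid geometry")
  expect_error(generateShape("sphere", R = 10, n = 10), "seed")
})

test_that("helix bead models produce the ~20 A A-helix P(r) peak", {
  h <- generateShape("helix", nBp = 16)
  q <- seq(0.008, 0.5, 0.004)
  p <- unitProfile(h, q)
  dm <- ceiling(max(dist(as.matrix(particles(h)[, c("x", "y", "z")])))) + 2
  pr <- iftPr(ScatteringProfile(qValues(p), intensities(p)), dmax = dm)
  peak <- rValues(pr)[which.max(prValues(pr))]
  expect_equal(peak, 20, tolerance = 3 / 20)
})

test_that("synthetic profiles: determinism, sqrt-exposure noise, background vs %D2O", {
  hp <- generateShape("hairpin", nBp = 12)
  p1 <- synthProfile(hp, x = 0.9, seed = 31)
  p2 <- synthProfile(hp, x = 0.9, seed = 31)
  expect_identical(intensities(p1), intensities(p2))
  p3 <- synthProfile(hp, x = 0.9, seed = 32)
  expect_false(identical(intensities(p1), intensities(p3)))
  ## exposure x4 halves sigma pointwise
  e1 <- synthProfile(hp, x = 0.9, exposure = 1, seed = 5)
  e4 <- synthProfile(hp, x = 0.9, exposure = 4, seed = 5)
  expect_equal(sigmas(e4), sigmas(e1) / 2, tolerance = 1e-12)
  ## incoherent background grows with the 1H content of the buffer
  b65 <- profileMetadata(synthProfile(hp, x = 0.65, seed = 5))$background
  b90 <- profileMetadata(synthProfile(hp, x = 0.90, seed = 5))$background
  expect_gt(b65, b90)
})

test_that("end-to-end recovery: sphere -> noisy profile -> Guinier", {
  sph <- generateShape("sphere", R = 20, n = 1200, seed = 5)
  q <- seq(0.008, 0.2, length.out = 120)
  truth <- sqrt(3 / 5) * 20
  ## high exposure: tight, nearly unbiased recovery (subset of replicates;
  ## the full 100-replicate bias check lives in the acceptance suite)
  hi <- t(vapply(1:25, function(i) {
    g <- guinierFit(synthProfile(sph, x = 1, exposure = 100,
                                 seed = 4000 + i, q = q))
    c(rgValue(g), rgError(g))
  }, numeric(2)))
  expect_equal(mean(hi[, 1]), truth, tolerance = 0.02)
  ## reported error consistent with replicate scatter within a factor of 2
  expect_gt(mean(hi[, 2]) / sd(hi[, 1]), 0.5)
  expect_lt(mean(hi[, 2]) / sd(hi[, 1]), 2)
  ## low exposure in protiated buffer (maximal incoherent background):
  ## errors grow; the estimate stays unbiased within the replicate scatter
  lo <- t(vapply(1:25, function(i) {
    ## at this noise level the quality criteria legitimately fail for some
    ## replicates and the fit falls back to the best window, with a warning
    g <- suppressWarnings(
      guinierFit(synthProfile(sph, x = 0, exposure = 0.5,
                              seed = 6000 + i, q = q)))
    c(rgValue(g), rgError(g))
  }, numeric(2)))
  expect_gt(mean(lo[, 2]), 3 * mean(hi[, 2]))  # error bars grew
  expect_lt(abs(mean(lo[, 1]) - truth),
            3 * sd(lo[, 1]) / sqrt(25) + 0.02 * truth)
})
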