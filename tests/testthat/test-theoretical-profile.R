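beadModel <- function(xyz, chain = "A", d = 0) {
  ch <- rep(chain, length.out = nrow(xyz))
  df <- data.frame(element = "BEAD", x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3], resid = "BEA", resno = seq_len(nrow(xyz)),
                   chain = ch, hNonexch = 0, hExch = 0, volume = 280)
  dd <- setNames(rep(d, length(unique(ch))), unique(ch))
  atomicModel(df, dd)
}

test_that("Debye closed forms: one and two particles", {
  m1 <- beadModel(matrix(0, 1, 3))
  p1 <- debyeIntensity(m1, c(0, 0.1, 0.3), contrasts = 1)
  expect_equal(intensities(p1), rep(1, 3))
  m2 <- beadModel(rbind(c(0, 0, 0), c(10, 0, 0)))
  q <- c(0, 0.05, 0.1, 0.2, 0.31)
  p2 <- debyeIntensity(m2, q, contrasts = c(1, 1))
  expected <- 2 * (1 + ifelse(q == 0, 1, sin(10 * q) / (10 * q)))
  expect_equal(intensities(p2), expected, tolerance = 1e-12)
  expect_equal(intensities(p2)[1], 4)  # I(0) = (sum f)^2
})

test_that("I(0) equals (sum of contrasts)^2 to machine precision", {
  set.seed(42)
  xyz <- matrix(rnorm(60 * 3, sd = 10), ncol = 3)
  f <- runif(60, -1, 2)
  m <- beadModel(xyz)
  for (meth in c("direct", "histogram")) {
    p <- debyeIntensity(m, c(0, 0.02, 0.05), contrasts = f, method = meth,
                        binWidth = 0.01)
    expect_equal(intensities(p)[1], sum(f)^2, tolerance = 1e-9, info = meth)
  }
})

test_that("profile is invariant under rigid rotation and translation", {
  set.seed(7)
  xyz <- matrix(rnorm(80 * 3, sd = 8), ncol = 3)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- sweep(xyz %*% rot, 2, c(5, -3, 11), "+")
  q <- seq(0, 0.4, 0.02)
  f <- runif(80)
  i1 <- intensities(debyeIntensity(beadModel(xyz), q, contrasts = f))
  i2 <- intensities(debyeIntensity(beadModel(xyz2), q, contrasts = f))
  expect_equal(i1, i2, tolerance = 1e-9)
})

test_that("histogram-accelerated Debye agrees with the direct sum", {
  sph <- generateShape("sphere", R = 20, n = 500, seed = 3)
  q <- seq(0.005, 0.3, length.out = 60)
  f <- rep(1, 500)
  pd <- debyeIntensity(sph, q, method = "direct", contrasts = f)
  ph <- debyeIntensity(sph, q, method = "histogram", binWidth = 0.1,
                       contrasts = f)
  expect_lt(max(abs(intensities(ph) / intensities(pd) - 1)), 0.005)
})

test_that("contrast assignment: vacuum limit, match-point nulling, perdeuterated excess", {
  tf <- miniPDB(tempfile(fileext = ".pdb"))
  m <- readPDB(tf, chainD = c(A = 0, B = 0))
  ## vacuum solvent: f = effective b including riding hydrogens
  p <- particles(m)
  f0 <- assignContrasts(m, x = 0) +
    solventSLD(0) * p$volume * 0.1           # strip solvent term back off
  bH <- -3.7406
  bExpected <- c(P = 5.13, O = 5.803, C = 6.6511 + 2 * bH,
                 N = 9.36 + bH, O2 = 5.803 + bH)
  expect_equal(f0[1:3], unname(bExpected[1:3]), tolerance = 1e-6)
  ## protiated bead chain at its own match point: total contrast vanishes
  hp <- generateShape("hairpin", nBp = 12)
  xstar <- matchPoint(averageRnaMolecule())
  fm <- assignContrasts(hp, x = xstar)
  expect_lt(abs(sum(fm)) / sum(abs(assignContrasts(hp, x = 0))), 0.01)
  ## perdeuterated chain in pure D2O scatters above solvent: f > 0
  hpD <- generateShape("hairpin", nBp = 12, chainD = c(A = 1))
  expect_true(all(assignContrasts(hpD, x = 1) > 0))
  ## unknown chain label is an error
  expect_error(atomicModel(particles(hp), c(Z = 0)), "cover all chains")
})

test_that("Guinier Rg of a simulated profile matches the contrast-weighted coordinate Rg", {
  sph <- generateShape("sphere", R = 18, n = 1500, seed = 21)
  f <- rep(1, 1500)
  q <- seq(0.004, 0.12, 0.002)   # qRg up to ~1.6, fit stays below 1.3
  pr <- debyeIntensity(sph, q, contrasts = f)
  g <- guinierFit(ScatteringProfile(q, intensities(pr)))
  expect_equal(rgValue(g), coordinateRg(sph, f), tolerance = 0.01)
})

test_that("CM simulation: masked complex collapses onto the visible chain", {
  cm <- generateShape("two_hairpin_complex", nBpA = 12, nBpB = 28,
                      chainD = c(A = 0, B = 1))
  xA <- matchPoint(averageRnaMolecule(d = 0))
  q <- seq(0.005, 0.25, length.out = 80)
  sim <- simulateCmSans(cm, q, x = xA)
  pc <- sim$complex; pb <- sim$chains[["B"]]
  ## chain A carries zero contrast, so complex == B-alone
  reg <- q * 26 <= 1.3
  expect_lt(max(abs(intensities(pc)[reg] / intensities(pb)[reg] - 1)), 0.05)
  ## Guinier Rg of the masked profile ~ visible chain's coordinate Rg
  ## (elongated chain: use the rod qRg ceiling)
  g <- guinierFit(ScatteringProfile(q, intensities(pc)), qRgMax = 1.0)
  pB <- particles(cm)[particles(cm)$chain == "B", ]
  rgB <- coordinateRg(atomicModel(pB, c(B = 1)))
  expect_equal(rgValue(g), rgB, tolerance = 0.03)
  ## both chains protiated at x = 0: complex equals merged single-chain sum
  cm0 <- generateShape("two_hairpin_complex", nBpA = 12, nBpB = 28)
  full <- debyeIntensity(cm0, q, x = 0)
  merged <- particles(cm0); merged$chain <- "A"
  one <- debyeIntensity(atomicModel(merged, c(A = 0)), q, x = 0)
  expect_equal(intensities(full), intensities(one), tolerance = 1e-9)
})
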