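# shared fixtures: analytic form factors and small builders

sphereFF <- function(q, R) {
  u <- q * R
  (3 * (sin(u) - u * cos(u)) / u^3)^2
}

# normalized solid-sphere distance distribution shape (up to scale)
sphereP <- function(r, R) {
  ifelse(r <= 2 * R, r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3)), 0)
}

sphereProfile <- function(R = 20, qmax = 0.35, dq = 0.004, qmin = 0.008,
                          sigma = FALSE) {
  q <- seq(qmin, qmax, dq)
  I <- sphereFF(q, R)
  ScatteringProfile(q, I, sigma = if (sigma) pmax(I, 1e-4) * 0.01
                                  else numeric(0))
}

gaussianProfile <- function(Rg = 15, I0 = 100, qmax = 0.35, dq = 0.002,
                            qmin = 0.005) {
  q <- seq(qmin, qmax, dq)
  ScatteringProfile(q, I0 * exp(-q^2 * Rg^2 / 3))
}

# equal-contrast bead profile
unitProfile <- function(model, q, ...) {
  pr <- debyeIntensity(model, q, contrasts = rep(1, nParticles(model)), ...)
  ScatteringProfile(qValues(pr), intensities(pr))
}

miniPDB <- function(path, element = TRUE) {
  lines <- c(
    "ATOM      1  P     G A   2      10.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  O5'   G A   2      11.000   1.000   0.000  1.00  0.00           O",
    "ATOM      3  C5'   G A   2      12.000   2.000   0.000  1.00  0.00           C",
    "ATOM      4  N1    G A   2      13.000   3.000   0.000  1.00  0.00           N",
    "ATOM      5  O2'   G A   2      13.500   3.500   0.500  1.00  0.00           O",
    "ATOM      6  C1'   U B   1       0.000   5.000   2.000  1.00  0.00           C",
    "ATOM      7  N3    U B   1       1.000   6.000   2.000  1.00  0.00           N",
    "ATOM      8  O3'   U B   1       2.000   7.000   2.000  1.00  0.00           O",
    "END")
  if (!element) lines <- sub("           [PONC]$", "", lines)
  writeLines(lines, path)
  path
}
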