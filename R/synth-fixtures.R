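## Coarse-grained coordinate fixtures (sphere, rod, A-form helix, hairpin,
## two-hairpin kissing complex) and SANS-like noisy synthetic profiles.
##
## The generator emulates the sample geometries of a small RNA contrast-
## matching study -- a compact ~30 nt hairpin, an elongated kinked hairpin
## and their loop-loop kissing complex -- and the two dominant SANS noise
## features: a flat incoherent background that grows with the solvent 1H
## content (1H incoherent cross-section ~40x that of 2H) and counting noise
## that shrinks with exposure.

.beadVolume <- function() {
  ref <- .beadReference()
  .moleculeVolume(ref) / sum(ref@inventory@residueCounts)
}

.beadFrame <- function(xyz, chain, resnoStart = 1) {
  n <- nrow(xyz)
  data.frame(element = "BEAD", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             resid = "BEA", resno = seq(resnoStart, length.out = n),
             chain = chain, hNonexch = 0, hExch = 0,
             volume = .beadVolume(), stringsAsFactors = FALSE)
}

## two-strand A-form helix bead trace: per base pair, one phosphate-trace
## bead per strand on a cylinder of the given diameter (strands ~150 deg
## apart in azimuth, axially staggered by one rise as in an antiparallel
## duplex), so an n-bp helix spans n * rise along the axis
.helixXYZ <- function(nBp, rise = .AHELIX_RISE, diameter = .AHELIX_DIAMETER,
                      twist = .AHELIX_TWIST) {
  if (nBp < 1) stop("nBp must be >= 1")
  R <- diameter / 2
  i <- seq_len(nBp) - 1
  phi <- i * twist * pi / 180
  z <- i * rise
  strand1 <- cbind(R * cos(phi), R * sin(phi), z)
  strand2 <- cbind(R * cos(phi + 150 * pi / 180),
                   R * sin(phi + 150 * pi / 180), z + rise)
  rbind(strand1, strand2)
}

## loop cap: arc of beads joining the two strand ends above the last bp
.loopXYZ <- function(nBp, nLoop = 4, rise = .AHELIX_RISE,
                     diameter = .AHELIX_DIAMETER, twist = .AHELIX_TWIST) {
  R <- diameter / 2
  phiTop <- (nBp - 1) * twist * pi / 180
  zTop <- (nBp - 0.5) * rise
  th <- seq(0, pi, length.out = nLoop + 2)[2:(nLoop + 1)]
  ## semicircle in the plane bisecting the two strand attachment points
  a0 <- phiTop; a1 <- phiTop + 150 * pi / 180
  cbind(R * cos(a0 + (a1 - a0) * th / pi),
        R * sin(a0 + (a1 - a0) * th / pi),
        zTop + 0.6 * R * sin(th))
}

#' Generate a coarse-grained coordinate fixture
#'
#' Deterministic (seeded) particle clouds for the standard test shapes:
#' \describe{
#'   \item{sphere}{\code{n} beads uniform in a ball of radius \code{R}.}
#'   \item{rod}{\code{n} beads uniform in a cylinder of the given
#'     \code{length} and \code{diameter}.}
#'   \item{helix}{two-strand coarse-grained A-form cylinder,
#'     \code{nBp} base pairs, configurable \code{rise} and \code{diameter}.}
#'   \item{hairpin}{helix plus an apical-loop bead cap.}
#'   \item{two_hairpin_complex}{two hairpins (chains A and B, \code{nBpA}/
#'     \code{nBpB} base pairs) joined loop-to-loop end-to-end along z with a
#'     configurable \code{bend} (degrees).}
#' }
#'
#' @param shape one of \code{"sphere"}, \code{"rod"}, \code{"helix"},
#'   \code{"hairpin"}, \code{"two_hairpin_complex"}.
#' @param R sphere radius, A.
#' @param n bead count for the random shapes (sphere, rod).
#' @param length rod length, A.
#' @param diameter rod/helix diameter, A.
#' @param nBp,nBpA,nBpB base-pair counts.
#' @param rise helix rise per bp, A.
#' @param bend complex bend angle at the junction, degrees.
#' @param chainD named deuteration labels (defaults: protiated; for the
#'   complex, \code{c(A = 0, B = 0)}).
#' @param seed integer; mandatory for the stochastic shapes.
#' @param packing sphere bead placement: \code{"random"} (seeded Monte
#'   Carlo) or \code{"lattice"} (deterministic cubic lattice, preferred for
#'   accuracy benchmarks against the analytic form factor).
#' @return an [AtomicModel-class] of bead particles.
#' @examples
#' generateShape("sphere", R = 20, n = 500, seed = 7)
#' generateShape("hairpin", nBp = 12)
#' @export
generateShape <- function(shape = c("sphere", "rod", "helix", "hairpin",
                                    "two_hairpin_complex"),
                          R = 20, n = 2000, length = 100,
                          diameter = .AHELIX_DIAMETER, nBp = 16,
                          nBpA = 12, nBpB = 28, rise = .AHELIX_RISE,
                          bend = 0, chainD = NULL, seed = NULL,
                          packing = c("random", "lattice")) {
  shape <- match.arg(shape)
  packing <- match.arg(packing)
  if (shape %in% c("sphere", "rod") &&
      !(shape == "sphere" && packing == "lattice")) {
    if (is.null(seed)) stop("seed is mandatory for stochastic shapes")
    set.seed(seed)
  }
  if (R <= 0 || length <= 0 || diameter <= 0 || nBp < 1 || rise <= 0)
    stop("invalid geometry")
  xyz <- switch(shape,
    sphere = {
      if (packing == "lattice") {
        ## deterministic cubic lattice filling the ball with ~n sites
        a <- (4 / 3 * pi * R^3 / n)^(1 / 3)
        g <- seq(-R, R, by = a)
        m <- as.matrix(expand.grid(x = g, y = g, z = g))
        m[rowSums(m^2) <= R^2, , drop = FALSE]
      } else {
        m <- matrix(stats::runif(3 * ceiling(n * 2.2), -R, R), ncol = 3)
        m <- m[rowSums(m^2) <= R^2, , drop = FALSE]
        while (nrow(m) < n) {
          m2 <- matrix(stats::runif(3 * n, -R, R), ncol = 3)
          m <- rbind(m, m2[rowSums(m2^2) <= R^2, , drop = FALSE])
        }
        m[seq_len(n), , drop = FALSE]
      }
    },
    rod = {
      r <- diameter / 2 * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th), stats::runif(n, 0, length))
    },
    helix = .helixXYZ(nBp, rise, diameter),
    hairpin = rbind(.helixXYZ(nBp, rise, diameter),
                    .loopXYZ(nBp, rise = rise, diameter = diameter)),
    two_hairpin_complex = NULL)

  if (shape == "two_hairpin_complex") {
    ## hairpins meet loop-to-loop: each is built with its loop at high z,
    ## chain A is reflected below z = 0, chain B (optionally bent) above
    a <- rbind(.helixXYZ(nBpA, rise, diameter),
               .loopXYZ(nBpA, rise = rise, diameter = diameter))
    b <- rbind(.helixXYZ(nBpB, rise, diameter),
               .loopXYZ(nBpB, rise = rise, diameter = diameter))
    gap <- 4
    a <- cbind(a[, 1], a[, 2], -(max(a[, 3]) - a[, 3]))    # loop at z = 0, body below
    b <- cbind(b[, 1], b[, 2], max(b[, 3]) - b[, 3] + gap) # loop at z = gap, body above
    if (bend != 0) {
      th <- bend * pi / 180
      rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0,
                      -sin(th), 0, cos(th)), 3, 3)
      b <- b %*% rot
      b[, 3] <- b[, 3] - min(b[, 3]) + gap
    }
    if (is.null(chainD)) chainD <- c(A = 0, B = 0)
    particles <- rbind(.beadFrame(a, "A"),
                       .beadFrame(b, "B", resnoStart = nrow(a) + 1))
    return(atomicModel(particles, chainD))
  }
  if (is.null(chainD)) chainD <- c(A = 0)
  atomicModel(.beadFrame(xyz, "A"), chainD)
}

#' Simulate a noisy SANS-like profile
#'
#' Computes the coherent Debye profile of the model at solvent composition
#' \code{x}, adds a flat incoherent background proportional to the solvent
#' 1H content (1H weighted 40x relative to 2H), and draws heteroscedastic
#' Gaussian noise with \code{sigma proportional to sqrt(I + background) /
#' sqrt(exposure)} (reduced, frame-averaged data; hence Gaussian rather
#' than Poisson).  By default the background mean is subtracted again --
#' emulating buffer subtraction, which removes the flat level but leaves
#' its noise -- so low-\%D2O conditions yield noisier, not offset, data;
#' set \code{subtractBackground = FALSE} to keep the offset.
#'
#' @param model an [AtomicModel-class].
#' @param x solvent D2O volume fraction.
#' @param q scattering vector grid, 1/A.
#' @param exposure relative counting time; sigma scales as 1/sqrt(exposure).
#' @param bgLevel incoherent background at x = 0 as a fraction of I(0).
#' @param exposureRef intensity scale used for the counting-noise variance.
#' @param subtractBackground logical (see Details).
#' @param fExch labile-exchange completeness.
#' @param seed integer; mandatory (fixes all randomness).
#' @param ... passed to [debyeIntensity()].
#' @return a [ScatteringProfile-class] with sigma populated and the
#'   background level recorded in its metadata.
#' @export
synthProfile <- function(model, x, q = seq(0.005, 0.35, length.out = 150),
                         exposure = 1, bgLevel = 0.01,
                         exposureRef = NULL, subtractBackground = TRUE,
                         fExch = .FEXCH_DEFAULT, seed, ...) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  set.seed(seed)
  coh <- debyeIntensity(model, q, x = x, fExch = fExch, ...)
  I <- coh@intensity
  ## the incoherent level is solvent-driven, so it scales with a contrast-
  ## independent reference (forward scattering in protiated buffer), not
  ## with the possibly contrast-matched coherent I(0)
  bgRef <- sum(assignContrasts(model, x = 0, fExch = fExch))^2
  hWeight <- (.INCOH_H_OVER_D * (1 - x) + x) / .INCOH_H_OVER_D
  bg <- bgLevel * bgRef * hWeight
  ref <- if (is.null(exposureRef)) 1e-3 * max(abs(I[1]), bg) else exposureRef
  sigma <- sqrt(pmax(I + bg, 0) * ref) / sqrt(exposure)
  sigma[sigma <= 0] <- min(sigma[sigma > 0], na.rm = TRUE)
  noisy <- I + bg + stats::rnorm(length(I), 0, sigma)
  if (subtractBackground) noisy <- noisy - bg
  ScatteringProfile(q = q, intensity = noisy, sigma = sigma,
                    metadata = list(solventX = x, exposure = exposure,
                                    background = bg, seed = seed,
                                    subtracted = subtractBackground))
}
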