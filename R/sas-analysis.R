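## Guinier fitting with automatic range selection, dimensionless Kratky
## transformation, Porod-volume molecular weight, logarithmic rebinning.

## weighted linear fit of ln I on q^2; returns slope/intercept, errors, r2
.guinierWLS <- function(q, I, sigma) {
  x <- q^2
  y <- log(I)
  w <- if (length(sigma)) (I / sigma)^2 else rep(1, length(I))
  W <- sum(w); xb <- sum(w * x) / W; yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  inter <- yb - slope * xb
  res <- y - (inter + slope * x)
  n <- length(x)
  s2 <- sum(w * res^2) / max(n - 2, 1)
  slopeErr <- sqrt(s2 / sxx)
  interErr <- sqrt(s2 * (1 / W + xb^2 / sxx))
  r2 <- 1 - sum(w * res^2) / sum(w * (y - yb)^2)
  ## Wald-Wolfowitz runs z-statistic on residual signs
  s <- sign(res); s <- s[s != 0]
  runs <- if (length(s) > 1) 1 + sum(diff(s) != 0) else 1
  np <- sum(s > 0); nn <- sum(s < 0)
  if (np > 0 && nn > 0) {
    mu <- 2 * np * nn / (np + nn) + 1
    v <- (mu - 1) * (mu - 2) / (np + nn - 1)
    runsZ <- if (v > 0) (runs - mu) / sqrt(v) else 0
  } else runsZ <- 0
  list(slope = slope, inter = inter, slopeErr = slopeErr,
       interErr = interErr, r2 = r2, runsZ = runsZ, res = res)
}

#' Guinier fit with automatic range selection
#'
#' Weighted least squares of \code{ln I} versus \code{q^2} over a low-q
#' window.  By default the window is chosen automatically: contiguous
#' windows of at least \code{minPoints} positive-intensity points are grown
#' self-consistently until \code{q_max * Rg} reaches the ceiling
#' (\code{qRgMax}; 1.3 for globular particles, 1.0 recommended for
#' elongated, rod-like ones), and among windows with \code{r^2 >= r2Min}
#' and an unsuspicious residual-runs statistic the longest is kept.
#' Parameter errors come from the covariance of the linear fit.
#'
#' @param profile a [ScatteringProfile-class]; non-positive intensities are
#'   excluded from the (log-space) fit.
#' @param qRgMax ceiling on q*Rg for the fitted window.
#' @param minPoints minimum number of points in a window.
#' @param r2Min minimum coefficient of determination for a window to be
#'   acceptable.
#' @param window optional fixed window \code{c(qmin, qmax)}; skips the
#'   automatic search.
#' @return a [GuinierResult-class].
#' @examples
#' q <- seq(0.01, 0.3, 0.002)
#' p <- ScatteringProfile(q, 100 * exp(-q^2 * 15^2 / 3))
#' guinierFit(p)
#' @export
guinierFit <- function(profile, qRgMax = 1.3, minPoints = 8, r2Min = 0.99,
                       window = NULL) {
  stopifnot(is(profile, "ScatteringProfile"))
  q <- profile@q; I <- profile@intensity; sg <- profile@sigma

  finish <- function(idx) {
    ft <- .guinierWLS(q[idx], I[idx],
                      if (length(sg)) sg[idx] else numeric(0))
    if (ft$slope >= 0) stop("no Guinier region: non-negative slope")
    rg <- sqrt(-3 * ft$slope)
    new("GuinierResult",
        rg = rg, rgErr = 3 * ft$slopeErr / (2 * rg),
        i0 = exp(ft$inter), i0Err = exp(ft$inter) * ft$interErr,
        qmin = min(q[idx]), qmax = max(q[idx]),
        qRgMax = max(q[idx]) * rg, r2 = ft$r2, nPoints = length(idx))
  }

  if (!is.null(window)) {
    idx <- which(q >= window[1] & q <= window[2] & I > 0)
    if (length(idx) < 3) stop("no Guinier region: fixed window too small")
    return(finish(idx))
  }

  pos <- which(I > 0)
  if (length(pos) < max(5, minPoints))
    stop("no Guinier region: too few positive-intensity points")

  ## crude initial Rg to bound candidate starts to the low-q regime
  init <- .guinierWLS(q[pos[1:max(5, minPoints)]],
                      I[pos[1:max(5, minPoints)]],
                      if (length(sg)) sg[pos[1:max(5, minPoints)]]
                      else numeric(0))
  rg0 <- if (init$slope < 0) sqrt(-3 * init$slope) else NA
  maxStart <- if (is.na(rg0)) length(pos) - minPoints + 1
              else max(1, sum(q[pos] * rg0 <= 0.5 * qRgMax) - minPoints + 1)
  maxStart <- min(maxStart, length(pos) - minPoints + 1)

  ## scan windows over both ends; a window is self-consistent when its own
  ## fitted Rg keeps q_max * Rg at or below the ceiling
  cands <- list()
  for (si in seq_len(max(1, maxStart))) {
    for (jj in (si + minPoints - 1):length(pos)) {
      idx <- pos[si:jj]
      ft <- .guinierWLS(q[idx], I[idx],
                        if (length(sg)) sg[idx] else numeric(0))
      if (ft$slope >= 0) break
      rg <- sqrt(-3 * ft$slope)
      if (max(q[idx]) * rg > qRgMax) break
      cands[[length(cands) + 1]] <-
        list(si = si, jj = jj, n = jj - si + 1, r2 = ft$r2,
             runsZ = ft$runsZ)
    }
  }
  if (!length(cands)) stop("no Guinier region found")
  ok <- Filter(function(cw) cw$r2 >= r2Min && abs(cw$runsZ) <= 3, cands)
  if (!length(ok)) {
    warning("no window met the fit-quality criteria; using best r2")
    ok <- cands[order(vapply(cands, `[[`, numeric(1), "r2"),
                      decreasing = TRUE)[1]]
  }
  ns <- vapply(ok, `[[`, numeric(1), "n")
  starts <- vapply(ok, `[[`, numeric(1), "si")
  best <- ok[[order(-ns, starts)[1]]]
  finish(pos[best$si:best$jj])
}

#' Dimensionless Kratky transform
#'
#' Transforms a profile to \code{(q Rg)^2 I(q)/I(0)} versus \code{q Rg}
#' using Guinier-derived Rg and I(0).  Compact globular particles peak near
#' \code{(sqrt(3), 3/e = 1.104)}; elongated or flexible chains plateau or
#' rise above that guideline and decay slowly.
#'
#' @param profile a [ScatteringProfile-class].
#' @param guinier a [GuinierResult-class] for the same profile.
#' @return data.frame with columns \code{qRg}, \code{y} and (when the
#'   profile carries uncertainties) \code{sigmaY}; the maximum is attached
#'   as attribute \code{peak} (list with \code{qRg}, \code{y}).
#' @export
dimensionlessKratky <- function(profile, guinier) {
  stopifnot(is(profile, "ScatteringProfile"), is(guinier, "GuinierResult"))
  if (guinier@i0 <= 0) stop("I(0) must be positive")
  qrg <- profile@q * guinier@rg
  y <- qrg^2 * profile@intensity / guinier@i0
  out <- data.frame(qRg = qrg, y = y)
  if (length(profile@sigma))
    out$sigmaY <- qrg^2 * profile@sigma / guinier@i0
  pk <- which.max(y)
  attr(out, "peak") <- list(qRg = qrg[pk], y = y[pk])
  out
}

#' Porod-volume molecular weight
#'
#' Porod invariant \code{Q = integral of q^2 I(q) dq from 0 to qCutoff}
#' (trapezoid on the data; the gap below the first measured point is filled
#' with the Guinier extrapolation), Porod volume \code{Vp = 2 pi^2 I(0)/Q},
#' and the concentration-independent molecular weight \code{Vp * density}.
#' Note that for sharp-interface particles the truncated invariant
#' converges slowly: at small \code{qCutoff * Rg} the volume (and MW) is
#' systematically overestimated.
#'
#' @param profile a [ScatteringProfile-class] extending at least to
#'   \code{qCutoff}.
#' @param guinier a [GuinierResult-class] supplying I(0) and Rg.
#' @param qCutoff upper integration limit, 1/A.
#' @param density macromolecule density, kDa/A^3.
#' @return list with \code{vp} (A^3), \code{mw} (kDa) and \code{Q}.
#' @export
porodMW <- function(profile, guinier, qCutoff = .POROD_QCUTOFF,
                    density = .POROD_DENSITY) {
  stopifnot(is(profile, "ScatteringProfile"), is(guinier, "GuinierResult"))
  q <- profile@q; I <- profile@intensity
  if (max(q) < qCutoff)
    stop(sprintf("data end at q = %.4g, short of the cutoff %.4g; achievable cutoff: %.4g",
                 max(q), qCutoff, max(q)))
  ## Guinier fill from 0 to the first data point
  qg <- seq(0, q[1], length.out = 64)
  Ig <- guinier@i0 * exp(-qg^2 * guinier@rg^2 / 3)
  Qlow <- sum(diff(qg) * (head(qg^2 * Ig, -1) + tail(qg^2 * Ig, -1)) / 2)
  ## data part up to the cutoff (interpolated endpoint)
  keep <- q <= qCutoff
  qq <- c(q[keep], qCutoff)
  II <- c(I[keep], approx(q, I, xout = qCutoff)$y)
  dup <- duplicated(qq)
  qq <- qq[!dup]; II <- II[!dup]
  y <- qq^2 * II
  Qdat <- sum(diff(qq) * (head(y, -1) + tail(y, -1)) / 2)
  Q <- Qlow + Qdat
  vp <- 2 * pi^2 * guinier@i0 / Q
  list(vp = vp, mw = vp * density, Q = Q)
}

#' Logarithmic rebinning
#'
#' Rebins a profile onto geometric q bins with a fixed number of points per
#' log decade (SANS reductions commonly use 33 or 66).  Per bin, intensity
#' is the inverse-variance-weighted mean, the reported q is the same
#' weighted mean of q, and sigma is propagated; empty bins are dropped.
#' Without uncertainties a plain mean is used.
#'
#' @param profile a [ScatteringProfile-class] with q > 0.
#' @param pointsPerDecade integer >= 1.
#' @return a rebinned [ScatteringProfile-class].
#' @export
logRebin <- function(profile, pointsPerDecade) {
  stopifnot(is(profile, "ScatteringProfile"))
  if (pointsPerDecade < 1) stop("pointsPerDecade must be >= 1")
  q <- profile@q; I <- profile@intensity; sg <- profile@sigma
  if (any(q <= 0)) {
    keep <- q > 0
    q <- q[keep]; I <- I[keep]
    if (length(sg)) sg <- sg[keep]
  }
  lo <- log10(min(q)); hi <- log10(max(q))
  edges <- 10^seq(lo - 1e-9, hi + 1e-9,
                  by = 1 / pointsPerDecade)
  if (max(edges) < max(q)) edges <- c(edges, max(q) * (1 + 1e-9))
  bin <- findInterval(q, edges, rightmost.closed = TRUE)
  w <- if (length(sg)) 1 / sg^2 else rep(1, length(q))
  sw <- rowsum(w, bin); bins <- as.integer(rownames(sw))
  qNew <- as.numeric(rowsum(w * q, bin) / sw)
  iNew <- as.numeric(rowsum(w * I, bin) / sw)
  sNew <- if (length(sg)) sqrt(1 / as.numeric(sw)) else numeric(0)
  md <- profile@metadata
  md$rebinnedPerDecade <- pointsPerDecade
  ScatteringProfile(q = qNew, intensity = iNew, sigma = sNew, metadata = md)
}
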