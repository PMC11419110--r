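## Optimal scaling of theoretical profiles onto experimental data and the
## reduced chi-square goodness of fit used to rank candidate models.

#' Fit a theoretical profile to experimental data
#'
#' Finds the multiplicative scale \code{c} (and, optionally, a flat
#' background \code{b}, recommended for SANS where residual incoherent
#' background survives subtraction) minimizing
#' \code{sum(((c I_calc + b - I_exp)/sigma)^2)} in closed form, and reports
#' the reduced chi-square (denominator \code{N - p}, \code{p} = number of
#' fitted parameters).  The calculated profile is linearly interpolated
#' onto the experimental q grid; points outside the calculated range are
#' excluded (no extrapolation).
#'
#' @param calc a [TheoreticalProfile-class] (or any
#'   [ScatteringProfile-class]) for the model.
#' @param exp a [ScatteringProfile-class] with positive uncertainties.
#' @param fitBackground logical; also fit a flat additive background.
#' @return a [FitResult-class].
#' @examples
#' q <- seq(0.01, 0.3, 0.005)
#' calc <- ScatteringProfile(q, exp(-q^2 * 75))
#' expd <- ScatteringProfile(q, 3 * exp(-q^2 * 75), sigma = rep(0.01, length(q)))
#' fitScale(calc, expd)
#' @export
fitScale <- function(calc, exp, fitBackground = FALSE) {
  stopifnot(is(calc, "ScatteringProfile"), is(exp, "ScatteringProfile"))
  if (!length(exp@sigma))
    stop("experimental profile has no uncertainties; weighted fit refused")
  keep <- exp@q >= min(calc@q) - 1e-12 & exp@q <= max(calc@q) + 1e-12
  if (!any(keep))
    stop("no overlap between calculated and experimental q ranges")
  qe <- exp@q[keep]; Ie <- exp@intensity[keep]; se <- exp@sigma[keep]
  Ic <- approx(calc@q, calc@intensity, xout = qe)$y
  if (all(Ic == 0)) stop("calculated profile is identically zero")
  w <- 1 / se^2
  if (fitBackground) {
    ## weighted least squares for (c, b)
    sww <- sum(w); swc <- sum(w * Ic); swc2 <- sum(w * Ic^2)
    swe <- sum(w * Ie); swce <- sum(w * Ic * Ie)
    den <- swc2 * sww - swc^2
    if (abs(den) < 1e-300) stop("degenerate background fit")
    cc <- (swce * sww - swc * swe) / den
    bb <- (swe - cc * swc) / sww
    p <- 2
  } else {
    cc <- sum(w * Ic * Ie) / sum(w * Ic^2)
    bb <- 0
    p <- 1
  }
  res <- (cc * Ic + bb - Ie) / se
  chi2 <- sum(res^2) / max(length(res) - p, 1)
  new("FitResult", scale = cc, background = bb,
      fitBackground = fitBackground, chi2 = chi2,
      nPoints = length(res), residuals = res)
}

#' Rank candidate models against one data set
#'
#' Fits every candidate theoretical profile to the experimental data with
#' [fitScale()] and returns a table ordered by chi-square (stable sort), with
#' the difference to the best model as an extra column: with noisy data the
#' absolute chi-square is deflated, but relative comparisons between models
#' fitted to the same data set remain meaningful.
#'
#' @param candidates named list of [TheoreticalProfile-class] objects.
#' @param exp a [ScatteringProfile-class].
#' @param fitBackground passed to [fitScale()].
#' @return data.frame with columns \code{model, chi2, deltaChi2, scale,
#'   background, nPoints, ok} sorted by chi2; candidates whose fit failed
#'   are retained with \code{ok = FALSE} and sorted last.
#' @export
rankModels <- function(candidates, exp, fitBackground = FALSE) {
  if (!length(candidates)) stop("need at least one candidate")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    names(candidates) <- paste0("model", seq_along(candidates))
  fits <- lapply(candidates, function(cd)
    tryCatch(fitScale(cd, exp, fitBackground = fitBackground),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(
    model = names(candidates),
    chi2 = vapply(seq_along(fits), function(i)
      if (ok[i]) fits[[i]]@chi2 else NA_real_, numeric(1)),
    scale = vapply(seq_along(fits), function(i)
      if (ok[i]) fits[[i]]@scale else NA_real_, numeric(1)),
    background = vapply(seq_along(fits), function(i)
      if (ok[i]) fits[[i]]@background else NA_real_, numeric(1)),
    nPoints = vapply(seq_along(fits), function(i)
      if (ok[i]) fits[[i]]@nPoints else NA_real_, numeric(1)),
    ok = ok)
  ord <- order(!tab$ok, tab$chi2)  # stable; failures last
  tab <- tab[ord, , drop = FALSE]
  tab$deltaChi2 <- tab$chi2 - tab$chi2[which(tab$ok)[1]]
  rownames(tab) <- NULL
  tab[, c("model", "chi2", "deltaChi2", "scale", "background",
          "nPoints", "ok")]
}
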