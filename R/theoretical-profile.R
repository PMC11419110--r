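## Theoretical SAXS/SANS profiles from atomic or bead coordinates via the
## Debye equation, with per-chain deuteration labels and solvent-exchange
## aware neutron contrasts.
##
## Hydrogens are implicit (riding on their heavy atoms); bead particles
## ("element" == "BEAD") represent one average nucleotide each, with
## scattering length and displaced volume taken from the equimolar
## reference molecule so that bead contrasts vanish exactly at the match
## point computed by matchPoint().

## equimolar average-nucleotide reference used by bead models
.beadReference <- function(d = 0, fExch = .FEXCH_DEFAULT,
                           vBar = .VBAR_RNA) {
  labeledMolecule(strrep(paste(.BEAD_RESIDUES, collapse = ""), 5),
                  d = d, fExch = fExch, vBar = vBar)
}

#' Equimolar average-RNA reference molecule
#'
#' A [LabeledMolecule-class] with equimolar A/C/G/U composition, used as
#' the per-bead scattering reference of coarse-grained models and as the
#' "average RNA" when quoting generic contrast match points.
#'
#' @param d,fExch,vBar see [labeledMolecule()].
#' @return a [LabeledMolecule-class].
#' @examples
#' matchPoint(averageRnaMolecule())   # protiated RNA matches near 65-70% D2O
#' @export
averageRnaMolecule <- function(d = 0, fExch = .FEXCH_DEFAULT,
                               vBar = .VBAR_RNA) {
  .beadReference(d = d, fExch = fExch, vBar = vBar)
}

.sinc <- function(z) {
  out <- z
  out[] <- 1
  big <- abs(z) >= 1e-4
  out[big] <- sin(z[big]) / z[big]
  small <- !big & z != 0
  out[small] <- 1 - z[small]^2 / 6
  out
}

#' Per-particle excess scattering lengths
#'
#' Effective coherent scattering length of every particle (heavy atom plus
#' riding hydrogens with the chain's deuteration and solvent exchange, or
#' average-nucleotide bead) minus the solvent term \code{rho_solv(x) * v_i}.
#'
#' @param model an [AtomicModel-class].
#' @param x solvent D2O volume fraction.
#' @param fExch labile-exchange completeness for the exchangeable riding
#'   hydrogens.
#' @return numeric vector of excess scattering lengths, fm.
#' @export
assignContrasts <- function(model, x = 0, fExch = .FEXCH_DEFAULT) {
  stopifnot(is(model, "AtomicModel"))
  p <- model@particles
  d <- model@chainD[p$chain]
  rhoS <- solventSLD(x)
  f <- numeric(nrow(p))
  isBead <- p$element == "BEAD"
  if (any(isBead)) {
    for (dv in unique(d[isBead])) {
      ref <- .beadReference(d = dv, fExch = fExch)
      nres <- sum(ref@inventory@residueCounts)
      sel <- isBead & d == dv
      ## per-nucleotide b; particle volume is stored per bead
      f[sel] <- .moleculeB(ref, x) / nres - rhoS * p$volume[sel] * 0.1
    }
  }
  if (any(!isBead)) {
    sel <- !isBead
    if (!all(p$element[sel] %in% names(.BCOH)))
      stop("unknown element(s): ",
           paste(setdiff(p$element[sel], names(.BCOH)), collapse = ", "))
    bH <- .BCOH[["H"]]; bD <- .BCOH[["D"]]
    bhvy <- .BCOH[p$element[sel]]
    fx <- fExch * x
    f[sel] <- bhvy +
      p$hNonexch[sel] * ((1 - d[sel]) * bH + d[sel] * bD) +
      p$hExch[sel] * ((1 - fx) * bH + fx * bD) -
      rhoS * p$volume[sel] * 0.1
  }
  unname(f)
}

## pair distances (lower triangle) and pair weights for a set of particles
.pairTerms <- function(xyz, f) {
  dvec <- as.numeric(stats::dist(xyz))
  wvec <- tcrossprod(f)[lower.tri(matrix(0, length(f), length(f)))]
  list(d = dvec, w = wvec)
}

## weighted pair-distance histogram accumulated in coordinate blocks, so
## large bead models never materialise the full n^2/2 pair list
.pairHistogram <- function(xyz, f, binWidth, block = 1024L) {
  n <- nrow(xyz)
  ## generous bin count from the bounding-box diagonal
  nb <- as.integer(ceiling(sqrt(sum((apply(xyz, 2, max) -
                                     apply(xyz, 2, min))^2)) / binWidth)) + 1L
  wb <- numeric(nb)
  starts <- seq(1L, n, by = block)
  sq <- rowSums(xyz^2)
  for (bi in seq_along(starts)) {
    i0 <- starts[bi]; i1 <- min(i0 + block - 1L, n)
    for (bj in bi:length(starts)) {
      j0 <- starts[bj]; j1 <- min(j0 + block - 1L, n)
      d2 <- outer(sq[i0:i1], sq[j0:j1], "+") -
        2 * tcrossprod(xyz[i0:i1, , drop = FALSE],
                       xyz[j0:j1, , drop = FALSE])
      d2[d2 < 0] <- 0
      wmat <- tcrossprod(f[i0:i1], f[j0:j1])
      if (bi == bj) {
        keep <- upper.tri(d2)
        dd <- sqrt(d2[keep]); ww <- wmat[keep]
      } else {
        dd <- sqrt(as.numeric(d2)); ww <- as.numeric(wmat)
      }
      idx <- pmin(nb, floor(dd / binWidth) + 1L)
      acc <- rowsum(ww, idx, reorder = TRUE)
      wb[as.integer(rownames(acc))] <-
        wb[as.integer(rownames(acc))] + as.numeric(acc)
    }
  }
  keep <- wb != 0
  list(r = ((seq_len(nb))[keep] - 0.5) * binWidth, w = wb[keep])
}

#' Debye-equation scattering profile
#'
#' Computes \code{I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij)} for the
#' model's particles with contrasts from [assignContrasts()].  The q -> 0
#' limit of the sinc kernel is evaluated by series, so \code{I(0) =
#' (sum f_i)^2} exactly.  For particle counts above \code{threshold} the
#' pair sum is accelerated by distance-histogram binning (bin width
#' \code{binWidth} A); \code{method} can force either path.
#'
#' @param model an [AtomicModel-class].
#' @param q scattering vector grid, 1/A (q >= 0).
#' @param x solvent D2O volume fraction.
#' @param fExch labile-exchange completeness.
#' @param method \code{"auto"}, \code{"direct"} or \code{"histogram"}.
#' @param binWidth histogram bin width, A.
#' @param threshold particle count above which \code{"auto"} switches to the
#'   histogram path.
#' @param contrasts optional precomputed per-particle scattering lengths
#'   (overrides \code{x}/\code{fExch}); used e.g. for vacuum profiles.
#' @return a [TheoreticalProfile-class].
#' @export
debyeIntensity <- function(model, q, x = 0, fExch = .FEXCH_DEFAULT,
                           method = c("auto", "direct", "histogram"),
                           binWidth = 0.1, threshold = 800,
                           contrasts = NULL) {
  stopifnot(is(model, "AtomicModel"))
  method <- match.arg(method)
  if (!is.numeric(q) || !length(q) || any(q < 0))
    stop("q must be non-negative")
  n <- nrow(model@particles)
  if (n < 1) stop("empty model")
  f <- if (is.null(contrasts)) assignContrasts(model, x, fExch) else contrasts
  if (length(f) != n) stop("contrast vector length mismatch")
  xyz <- as.matrix(model@particles[, c("x", "y", "z")])
  self <- sum(f^2)
  if (n == 1) {
    I <- rep(self, length(q))
  } else {
    if (method == "auto")
      method <- if (n > threshold) "histogram" else "direct"
    if (method == "direct") {
      pt <- .pairTerms(xyz, f)
      I <- self + 2 * vapply(q, function(qq) sum(pt$w * .sinc(qq * pt$d)),
                             numeric(1))
    } else {
      h <- .pairHistogram(xyz, f, binWidth)
      I <- self + 2 * as.numeric(.sinc(outer(q, h$r)) %*% h$w)
    }
  }
  new("TheoreticalProfile", q = as.numeric(q), intensity = I,
      sigma = numeric(0),
      metadata = list(nParticles = n, solventX = x,
                      chainD = model@chainD, method = method))
}

#' Simulate contrast-matched SANS of a labelled complex
#'
#' Full-complex Debye profile of a multi-chain model at the given solvent
#' composition, with companion single-chain profiles computed at the same
#' contrast for masking diagnostics: at the match point of one chain, the
#' complex profile should collapse onto the other chain's profile.
#'
#' @param model an [AtomicModel-class] with two (or more) chains and
#'   per-chain deuteration labels.
#' @param q scattering vector grid, 1/A.
#' @param x solvent D2O volume fraction.
#' @param fExch labile-exchange completeness.
#' @param ... passed to [debyeIntensity()].
#' @return list with elements \code{complex} (a
#'   [TheoreticalProfile-class]) and \code{chains} (named list of
#'   single-chain profiles at the same contrast).
#' @export
simulateCmSans <- function(model, q, x, fExch = .FEXCH_DEFAULT, ...) {
  stopifnot(is(model, "AtomicModel"))
  chains <- unique(model@particles$chain)
  if (length(chains) < 2)
    stop("need a complex with at least two chains")
  full <- debyeIntensity(model, q, x = x, fExch = fExch, ...)
  single <- lapply(chains, function(ch) {
    sub <- model@particles[model@particles$chain == ch, , drop = FALSE]
    m <- atomicModel(sub, model@chainD[ch])
    debyeIntensity(m, q, x = x, fExch = fExch, ...)
  })
  names(single) <- chains
  list(complex = full, chains = single)
}

#' Contrast-weighted coordinate radius of gyration
#'
#' \code{sqrt(sum f r^2 / sum f - |sum f r / sum f|^2)} over the particles;
#' with unit weights this is the plain coordinate Rg.  The oracle against
#' which Guinier fits of simulated profiles are checked.
#'
#' @param model an [AtomicModel-class].
#' @param weights optional per-particle weights (default: equal).
#' @return Rg in A.
#' @export
coordinateRg <- function(model, weights = NULL) {
  xyz <- as.matrix(model@particles[, c("x", "y", "z")])
  w <- if (is.null(weights)) rep(1, nrow(xyz)) else weights
  com <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)) / sum(w))
}
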