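#' @import methods
NULL

## ---------------------------------------------------------------------------
## AtomInventory

#' AtomInventory: element counts of a nucleic acid
#'
#' Element counts of an RNA chain with hydrogens split into the exchangeable
#' (N/O-bonded, solvent-labile) and non-exchangeable (carbon-bonded) classes,
#' plus the protiated molecular mass.  Phosphates are treated as ionized
#' (no acidic protons), the convention appropriate at neutral pH.
#'
#' @slot counts named numeric; heavy-element counts (C, N, O, P).
#' @slot hNonexch numeric(1); carbon-bonded hydrogens.
#' @slot hExch numeric(1); N/O-bonded hydrogens (includes each 2'-OH and
#'   terminal hydroxyl protons).
#' @slot massProtiated numeric(1); molecular weight of the fully protiated
#'   chain, kDa.
#' @slot residueCounts named numeric; counts of A, C, G, U.
#' @slot termini character(2); the 5' and 3' end chemistry.
#' @exportClass AtomInventory
setClass("AtomInventory",
  representation(counts = "numeric", hNonexch = "numeric", hExch = "numeric",
                 massProtiated = "numeric", residueCounts = "numeric",
                 termini = "character"),
  validity = function(object) {
    msg <- NULL
    if (!all(c("C", "N", "O", "P") %in% names(object@counts)))
      msg <- c(msg, "counts must be named C, N, O, P")
    if (any(object@counts < 0) || object@hNonexch < 0 || object@hExch < 0)
      msg <- c(msg, "negative atom count")
    n <- sum(object@residueCounts)
    if (n >= 1 && object@hExch < n)
      msg <- c(msg, "fewer exchangeable hydrogens than residues (2'-OH missing?)")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## LabeledMolecule

#' LabeledMolecule: an inventory plus isotope-labelling state
#'
#' An [AtomInventory-class] together with the fraction \code{d} of
#' non-exchangeable hydrogens replaced by deuterium, the effective
#' completeness \code{fExch} of labile-hydrogen exchange with solvent, and
#' the partial specific volume \code{vBar} used to convert mass to excluded
#' volume.  This is the object whose neutron scattering length density is
#' computed by [moleculeSLD()].
#'
#' @slot inventory an [AtomInventory-class].
#' @slot d numeric(1) in \[0, 1\]; non-exchangeable deuteration fraction.
#' @slot fExch numeric(1) in \[0, 1\]; labile-exchange completeness.
#' @slot vBar numeric(1), cm^3/g; partial specific volume.
#' @exportClass LabeledMolecule
setClass("LabeledMolecule",
  representation(inventory = "AtomInventory", d = "numeric",
                 fExch = "numeric", vBar = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@d < 0 || object@d > 1) msg <- c(msg, "d must lie in [0, 1]")
    if (object@fExch < 0 || object@fExch > 1)
      msg <- c(msg, "fExch must lie in [0, 1]")
    if (object@vBar <= 0) msg <- c(msg, "vBar must be positive")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## ScatteringProfile

#' ScatteringProfile: a reduced 1-D scattering curve
#'
#' Momentum transfer \code{q} (1/A, strictly increasing), intensity
#' \code{I(q)} (arbitrary units) and, optionally, the pointwise uncertainty
#' \code{sigma}.  The unit of all analysis and fitting in the package.
#'
#' @slot q numeric; scattering vector, 1/A, strictly increasing, >= 0.
#' @slot intensity numeric; same length as \code{q}.
#' @slot sigma numeric; uncertainties (length 0 when absent).
#' @slot metadata list; free-form provenance (sample, solvent x, source).
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@q) < 3) msg <- c(msg, "need at least 3 points")
    if (length(object@intensity) != length(object@q))
      msg <- c(msg, "q and intensity lengths differ")
    if (length(object@sigma) && length(object@sigma) != length(object@q))
      msg <- c(msg, "sigma length differs from q")
    if (any(object@q < 0)) msg <- c(msg, "q must be non-negative")
    if (is.unsorted(object@q, strictly = TRUE))
      msg <- c(msg, "q must be strictly increasing")
    if (length(object@sigma) && any(object@sigma <= 0))
      msg <- c(msg, "sigma must be positive where present")
    if (is.null(msg)) TRUE else msg
  })

#' TheoreticalProfile: a back-calculated scattering curve
#'
#' A [ScatteringProfile-class] computed from coordinates by the Debye
#' equation; carries provenance (solvent composition, chain labels, model
#' hash) in its metadata and normally has no \code{sigma}.
#'
#' @exportClass TheoreticalProfile
setClass("TheoreticalProfile", contains = "ScatteringProfile")

## ---------------------------------------------------------------------------
## AtomicModel

#' AtomicModel: coordinates with isotope labels
#'
#' Particle table (element or bead class, coordinates in A, residue and
#' chain identifiers, implicit riding-hydrogen counts, displaced volume) plus
#' a per-chain deuteration label.  Input to the Debye simulation.
#'
#' @slot particles data.frame with columns \code{element, x, y, z, resid,
#'   resno, chain, hNonexch, hExch, volume}.
#' @slot chainD named numeric; non-exchangeable deuteration fraction per
#'   chain; names must cover every chain present.
#' @exportClass AtomicModel
setClass("AtomicModel",
  representation(particles = "data.frame", chainD = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("element", "x", "y", "z", "resid", "resno", "chain",
              "hNonexch", "hExch", "volume")
    if (!all(need %in% names(object@particles)))
      msg <- c(msg, paste("particles must have columns:",
                          paste(need, collapse = ", ")))
    else {
      xyz <- as.matrix(object@particles[, c("x", "y", "z")])
      if (!all(is.finite(xyz))) msg <- c(msg, "non-finite coordinates")
      if (any(object@particles$volume <= 0))
        msg <- c(msg, "displaced volumes must be positive")
      ch <- unique(object@particles$chain)
      if (!all(ch %in% names(object@chainD)))
        msg <- c(msg, "chainD labels must cover all chains")
    }
    if (length(object@chainD) &&
        (any(object@chainD < 0) || any(object@chainD > 1)))
      msg <- c(msg, "chain deuteration labels must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## results

#' GuinierResult: parameters of a Guinier fit
#'
#' @slot rg,rgErr numeric(1); radius of gyration and its standard error, A.
#' @slot i0,i0Err numeric(1); forward scattering and standard error.
#' @slot qmin,qmax numeric(1); fitted window limits, 1/A.
#' @slot qRgMax numeric(1); q*Rg at the window's upper edge.
#' @slot r2 numeric(1); coefficient of determination of the linear fit.
#' @slot nPoints numeric(1); points in the window.
#' @exportClass GuinierResult
setClass("GuinierResult",
  representation(rg = "numeric", rgErr = "numeric", i0 = "numeric",
                 i0Err = "numeric", qmin = "numeric", qmax = "numeric",
                 qRgMax = "numeric", r2 = "numeric", nPoints = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@rg <= 0) msg <- c(msg, "Rg must be positive")
    if (object@qmin >= object@qmax) msg <- c(msg, "qmin must be < qmax")
    if (is.null(msg)) TRUE else msg
  })

#' ContrastCurve: tabulated contrast versus solvent composition
#'
#' @slot x numeric; D2O volume-fraction grid.
#' @slot rhoMol,rhoSolv,deltaRho numeric; SLDs and contrast, 1e-6 A^-2.
#' @slot matchPoint numeric(1); x where deltaRho = 0, or NA.
#' @slot matchFlag character(1); "matched", "above-range", "below-range".
#' @exportClass ContrastCurve
setClass("ContrastCurve",
  representation(x = "numeric", rhoMol = "numeric", rhoSolv = "numeric",
                 deltaRho = "numeric", matchPoint = "numeric",
                 matchFlag = "character"))

#' PofR: pair-distance distribution
#'
#' Real-space distance distribution recovered by the regularized indirect
#' Fourier transform, with endpoint zeros enforced at r = 0 and r = Dmax.
#'
#' @slot r numeric; distance grid on \[0, Dmax\], A.
#' @slot pr numeric; P(r), arbitrary scale.
#' @slot dmax numeric(1), A.
#' @slot alpha numeric(1); regularization weight used.
#' @slot rgReal,i0Real numeric(1); real-space Rg (A) and I(0).
#' @slot chi2 numeric(1); reduced chi-square of the back-transformed fit.
#' @slot quality list; descriptors (positivity fraction, endpoint closeness,
#'   smoothness).
#' @exportClass PofR
setClass("PofR",
  representation(r = "numeric", pr = "numeric", dmax = "numeric",
                 alpha = "numeric", rgReal = "numeric", i0Real = "numeric",
                 chi2 = "numeric", quality = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@r) != length(object@pr))
      msg <- c(msg, "r and pr lengths differ")
    if (object@dmax <= 0) msg <- c(msg, "Dmax must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' FitResult: model-to-data goodness of fit
#'
#' @slot scale numeric(1); optimal multiplicative scale.
#' @slot background numeric(1); fitted flat background (0 when not fitted).
#' @slot fitBackground logical(1).
#' @slot chi2 numeric(1); reduced chi-square.
#' @slot nPoints numeric(1); points compared.
#' @slot residuals numeric; (c*Icalc + b - Iexp)/sigma.
#' @exportClass FitResult
setClass("FitResult",
  representation(scale = "numeric", background = "numeric",
                 fitBackground = "logical", chi2 = "numeric",
                 nPoints = "numeric", residuals = "numeric"),
  validity = function(object) {
    if (object@chi2 < 0) "chi2 must be non-negative" else TRUE
  })
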