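#' Accessors for nucsolv classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{qValues}, \code{intensities}, \code{sigmas} and
#' \code{profileMetadata} for [ScatteringProfile-class];
#' \code{particles}, \code{chainLabels} and \code{nParticles} for
#' [AtomicModel-class]; \code{rgValue}, \code{rgError}, \code{i0Value}
#' for [GuinierResult-class] and [PofR-class]; \code{dmaxValue},
#' \code{rValues}, \code{prValues} for [PofR-class]; \code{chiSquare},
#' \code{scaleFactor} for [FitResult-class]; \code{matchPointValue} for
#' [ContrastCurve-class].
#'
#' @param object an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases qValues intensities sigmas profileMetadata particles chainLabels
#'   nParticles rgValue rgError i0Value i0Error dmaxValue rValues prValues
#'   chiSquare scaleFactor matchPointValue
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sigmas", function(object) standardGeneric("sigmas"))
#' @rdname accessors
#' @export
setGeneric("profileMetadata",
           function(object) standardGeneric("profileMetadata"))
#' @rdname accessors
#' @export
setGeneric("particles", function(object) standardGeneric("particles"))
#' @rdname accessors
#' @export
setGeneric("chainLabels", function(object) standardGeneric("chainLabels"))
#' @rdname accessors
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("rgValue", function(object) standardGeneric("rgValue"))
#' @rdname accessors
#' @export
setGeneric("rgError", function(object) standardGeneric("rgError"))
#' @rdname accessors
#' @export
setGeneric("i0Value", function(object) standardGeneric("i0Value"))
#' @rdname accessors
#' @export
setGeneric("i0Error", function(object) standardGeneric("i0Error"))
#' @rdname accessors
#' @export
setGeneric("dmaxValue", function(object) standardGeneric("dmaxValue"))
#' @rdname accessors
#' @export
setGeneric("rValues", function(object) standardGeneric("rValues"))
#' @rdname accessors
#' @export
setGeneric("prValues", function(object) standardGeneric("prValues"))
#' @rdname accessors
#' @export
setGeneric("chiSquare", function(object) standardGeneric("chiSquare"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(object) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("matchPointValue",
           function(object) standardGeneric("matchPointValue"))

setMethod("qValues", "ScatteringProfile", function(object) object@q)
setMethod("intensities", "ScatteringProfile", function(object) object@intensity)
setMethod("sigmas", "ScatteringProfile", function(object) object@sigma)
setMethod("profileMetadata", "ScatteringProfile",
          function(object) object@metadata)
setMethod("particles", "AtomicModel", function(object) object@particles)
setMethod("chainLabels", "AtomicModel", function(object) object@chainD)
setMethod("nParticles", "AtomicModel", function(object) nrow(object@particles))
setMethod("rgValue", "GuinierResult", function(object) object@rg)
setMethod("rgError", "GuinierResult", function(object) object@rgErr)
setMethod("i0Value", "GuinierResult", function(object) object@i0)
setMethod("i0Error", "GuinierResult", function(object) object@i0Err)
setMethod("rgValue", "PofR", function(object) object@rgReal)
setMethod("i0Value", "PofR", function(object) object@i0Real)
setMethod("dmaxValue", "PofR", function(object) object@dmax)
setMethod("rValues", "PofR", function(object) object@r)
setMethod("prValues", "PofR", function(object) object@pr)
setMethod("chiSquare", "PofR", function(object) object@chi2)
setMethod("chiSquare", "FitResult", function(object) object@chi2)
setMethod("scaleFactor", "FitResult", function(object) object@scale)
setMethod("matchPointValue", "ContrastCurve", function(object) object@matchPoint)

## length of a profile = number of q points
#' @export
setMethod("length", "ScatteringProfile", function(x) length(x@q))

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("%s with %d points, q in [%.4g, %.4g] 1/A, sigma %s\n",
              class(object), length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) "present" else "absent"))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "AtomicModel", function(object) {
  ch <- table(object@particles$chain)
  cat(sprintf("AtomicModel: %d particles, %d chain(s)\n",
              nrow(object@particles), length(ch)))
  for (nm in names(ch))
    cat(sprintf("  chain %s: %d particles, d = %.2f\n",
                nm, ch[[nm]], object@chainD[[nm]]))
})

setMethod("show", "AtomInventory", function(object) {
  cat(sprintf(
    "AtomInventory: n = %d (A%d C%d G%d U%d), termini %s/%s\n",
    sum(object@residueCounts),
    object@residueCounts[["A"]], object@residueCounts[["C"]],
    object@residueCounts[["G"]], object@residueCounts[["U"]],
    object@termini[1], object@termini[2]))
  cat(sprintf("  C%d N%d O%d P%d; H: %d non-exchangeable + %d exchangeable\n",
              object@counts[["C"]], object@counts[["N"]],
              object@counts[["O"]], object@counts[["P"]],
              object@hNonexch, object@hExch))
  cat(sprintf("  protiated MW: %.3f kDa\n", object@massProtiated))
})

setMethod("show", "LabeledMolecule", function(object) {
  cat(sprintf(
    "LabeledMolecule: d = %.3f, fExch = %.2f, vBar = %.3f cm^3/g\n",
    object@d, object@fExch, object@vBar))
  show(object@inventory)
})

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf(
    "Guinier fit: Rg = %.3f +- %.3f A, I(0) = %.4g +- %.2g\n",
    object@rg, object@rgErr, object@i0, object@i0Err))
  cat(sprintf("  window q = [%.4g, %.4g] (%d pts), qRg(max) = %.3f, r2 = %.5f\n",
              object@qmin, object@qmax, object@nPoints, object@qRgMax,
              object@r2))
})

setMethod("show", "ContrastCurve", function(object) {
  cat(sprintf("ContrastCurve over %d solvent compositions\n",
              length(object@x)))
  if (is.na(object@matchPoint))
    cat(sprintf("  no match point in [0, 1] (%s)\n", object@matchFlag))
  else
    cat(sprintf("  match point: %.1f%% D2O\n", 100 * object@matchPoint))
})

setMethod("show", "PofR", function(object) {
  cat(sprintf(
    "P(r): Dmax = %.1f A, alpha = %.3g, Rg = %.2f A, I(0) = %.4g, chi2 = %.3g\n",
    object@dmax, object@alpha, object@rgReal, object@i0Real, object@chi2))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "Profile fit: chi2 = %.4g (n = %d), scale = %.4g, background = %.4g%s\n",
    object@chi2, object@nPoints, object@scale, object@background,
    if (object@fitBackground) " (fitted)" else ""))
})
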