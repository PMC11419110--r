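## Neutron scattering length densities of H2O/D2O mixtures and (partially)
## deuterated RNA; contrast curves and match points.
##
## All SLDs are in units of 1e-6 A^-2.  Both the molecule and the solvent
## SLD are affine in the D2O volume fraction x, so match points and required
## deuterations have closed forms.

#' Construct a LabeledMolecule
#'
#' @param x an RNA sequence string, residue-count vector, or
#'   [AtomInventory-class].
#' @param d fraction of non-exchangeable hydrogens replaced by 2H, \[0, 1\].
#' @param fExch effective completeness of labile-hydrogen exchange with the
#'   solvent, \[0, 1\].  The default (0.88) is calibrated for structured
#'   (helical) RNA, where imino/amino protons engaged in Watson-Crick pairs
#'   exchange incompletely; use 1 for fully solvent-equilibrated labile sites.
#' @param vBar partial specific volume, cm^3/g.
#' @param ... termini arguments passed to [atomInventory()] when \code{x} is
#'   a sequence.
#' @return a [LabeledMolecule-class].
#' @examples
#' labeledMolecule("GGGCGGUGGUGCCCCCCCGCGUCAGCGCG", d = 0.42)
#' @export
labeledMolecule <- function(x, d = 0, fExch = .FEXCH_DEFAULT,
                            vBar = .VBAR_RNA, ...) {
  inv <- if (is(x, "AtomInventory")) x else atomInventory(x, ...)
  obj <- new("LabeledMolecule", inventory = inv, d = d, fExch = fExch,
             vBar = vBar)
  validObject(obj)
  obj
}

.sldWater <- function(species) {
  w <- .WATER[[species]]
  b <- if (species == "D2O") 2 * .BCOH[["D"]] + .BCOH[["O"]]
       else 2 * .BCOH[["H"]] + .BCOH[["O"]]
  vol <- w$mass / (w$density * .AVOGADRO) * 1e24   # A^3 per molecule
  b * 1e-5 / vol * 1e6                             # 1e-6 A^-2
}

#' Solvent scattering length density
#'
#' SLD of an H2O:D2O mixture by ideal (additive-volume) mixing of the pure
#' components at 20 C.
#'
#' @param x D2O volume fraction in \[0, 1\] (vectorized).
#' @return SLD in 1e-6 A^-2.
#' @examples
#' solventSLD(c(0, 0.65, 1))
#' @export
solventSLD <- function(x) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1))
    stop("D2O volume fraction must lie in [0, 1]")
  x * .sldWater("D2O") + (1 - x) * .sldWater("H2O")
}

## total coherent scattering length (fm) of a labeled molecule at solvent x
.moleculeB <- function(m, x) {
  inv <- m@inventory
  heavy <- sum(inv@counts * .BCOH[c("C", "N", "O", "P")])
  bn <- inv@hNonexch * ((1 - m@d) * .BCOH[["H"]] + m@d * .BCOH[["D"]])
  fx <- m@fExch * x
  be <- inv@hExch * ((1 - fx) * .BCOH[["H"]] + fx * .BCOH[["D"]])
  heavy + bn + be
}

## excluded volume in A^3, held constant under deuteration (protiated mass)
.moleculeVolume <- function(m) {
  m@inventory@massProtiated * 1000 * m@vBar / .AVOGADRO * 1e24
}

#' Molecule scattering length density
#'
#' Neutron SLD of a (partially) deuterated RNA in an H2O:D2O mixture.
#' Exchangeable hydrogens carry solvent isotope composition to completeness
#' \code{fExch}; the excluded volume is the protiated mass times \code{vBar}
#' and is held constant under deuteration (only mass and density change on
#' 1H to 2H replacement).
#'
#' @param m a [LabeledMolecule-class].
#' @param x D2O volume fraction in \[0, 1\] (vectorized).
#' @return SLD in 1e-6 A^-2.
#' @examples
#' m <- labeledMolecule("GGGCGGUGGUGCCCCCCCGCGUCAGCGCG", d = 0.42)
#' moleculeSLD(m, c(0, 1))
#' @export
moleculeSLD <- function(m, x) {
  stopifnot(is(m, "LabeledMolecule"))
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1))
    stop("D2O volume fraction must lie in [0, 1]")
  vapply(x, function(xi) .moleculeB(m, xi), numeric(1)) * 1e-5 /
    .moleculeVolume(m) * 1e6
}

#' Contrast match point
#'
#' Solves \code{moleculeSLD(m, x) = solventSLD(x)} in closed form (both
#' sides are affine in x).  Returns the matching D2O fraction, or \code{NA}
#' with a flag attribute (\code{"above-range"} / \code{"below-range"}) when
#' the solution lies outside \[0, 1\] -- e.g. perdeuterated RNA, whose SLD
#' exceeds that of pure D2O.
#'
#' @param m a [LabeledMolecule-class].
#' @return matching x in \[0, 1\], or NA with attribute \code{flag}.
#' @examples
#' matchPoint(labeledMolecule("GGGCGGUGGUGCCCCCCCGCGUCAGCGCG", d = 0.42))
#' @export
matchPoint <- function(m) {
  r0 <- moleculeSLD(m, 0); r1 <- moleculeSLD(m, 1)
  s0 <- solventSLD(0); s1 <- solventSLD(1)
  dslope <- (r1 - r0) - (s1 - s0)
  if (abs(dslope) < 1e-12) {
    if (abs(s0 - r0) < 1e-12) stop("everywhere matched: identical SLD lines")
    xstar <- Inf
  } else {
    xstar <- (s0 - r0) / dslope
  }
  if (xstar < 0 || xstar > 1) {
    structure(NA_real_,
              flag = if (xstar > 1) "above-range" else "below-range")
  } else xstar
}

#' Deuteration required for a target match point
#'
#' Smallest non-exchangeable deuteration fraction \code{d} for which the
#' molecule's contrast match point equals \code{targetX}; closed form from
#' the affine SLD model.  Returns \code{NA} with an explanatory flag when
#' the target is unreachable with \code{d} in \[0, 1\].
#'
#' @param inv an [AtomInventory-class] (or sequence string).
#' @param targetX desired match point, D2O volume fraction in \[0, 1\].
#' @param fExch,vBar as in [labeledMolecule()].
#' @return d in \[0, 1\], or NA with attribute \code{flag}.
#' @examples
#' requiredDeuteration("GGGCGGUGGUGCCCCCCCGCGUCAGCGCG", 0.90)
#' @export
requiredDeuteration <- function(inv, targetX, fExch = .FEXCH_DEFAULT,
                                vBar = .VBAR_RNA) {
  if (!is.numeric(targetX) || length(targetX) != 1 ||
      targetX < 0 || targetX > 1)
    stop("targetX must lie in [0, 1]")
  m0 <- labeledMolecule(inv, d = 0, fExch = fExch, vBar = vBar)
  ## rho_mol(d, x) = rho_mol(0, x) + d * hn * (bD - bH) / V (in 1e-6 A^-2)
  hnTerm <- m0@inventory@hNonexch * (.BCOH[["D"]] - .BCOH[["H"]]) * 1e-5 /
    .moleculeVolume(m0) * 1e6
  need <- solventSLD(targetX) - moleculeSLD(m0, targetX)
  d <- need / hnTerm
  if (d < -1e-9 || d > 1 + 1e-9)
    return(structure(NA_real_,
                     flag = if (d > 1) "deuteration > 1 required"
                            else "already above solvent SLD"))
  min(max(d, 0), 1)
}

#' Tabulated contrast curve
#'
#' Molecule SLD, solvent SLD and contrast over a grid of D2O fractions,
#' with the match point from [matchPoint()].
#'
#' @param m a [LabeledMolecule-class].
#' @param x grid of D2O volume fractions within \[0, 1\], at least 2 points.
#' @return a [ContrastCurve-class].
#' @examples
#' contrastCurve(labeledMolecule("GGGCGGUGGUGCCCCCCCGCGUCAGCGCG"))
#' @export
contrastCurve <- function(m, x = seq(0, 1, by = 0.01)) {
  if (length(x) < 2) stop("grid needs at least 2 points")
  rhoM <- moleculeSLD(m, x)
  rhoS <- solventSLD(x)
  mp <- matchPoint(m)
  new("ContrastCurve", x = x, rhoMol = rhoM, rhoSolv = rhoS,
      deltaRho = rhoM - rhoS,
      matchPoint = as.numeric(mp),
      matchFlag = if (is.na(mp)) attr(mp, "flag") else "matched")
}

#' Convert a ContrastCurve to a data.frame
#'
#' @param x a [ContrastCurve-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns x, rhoMol, rhoSolv, deltaRho.
#' @export
as.data.frame.ContrastCurve <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(x = x@x, rhoMol = x@rhoMol, rhoSolv = x@rhoSolv,
             deltaRho = x@deltaRho)
}
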