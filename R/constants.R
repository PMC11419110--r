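# Physical constants and element/residue tables.
#
# Every scattering length, atomic mass, displaced volume and calibrated
# default used anywhere in the package lives here; no literals are scattered
# through the modules.  Coherent neutron scattering lengths are the standard
# bound values (Sears tabulation), in fm.  SLDs are handled internally in
# units of 1e-6 A^-2 throughout (note: some publications print "A^-2" while
# omitting the 1e-6 factor).

#' @name nucsolv-constants
#' @title Physical constants used by nucsolv
#' @description Internal tables: coherent scattering lengths (fm), atomic
#'   masses (Da), displaced atomic volumes (A^3), ribonucleotide composition
#'   templates with exchangeable/non-exchangeable hydrogen classes, and the
#'   calibrated defaults for the RNA partial specific volume and labile
#'   hydrogen exchange completeness.
#' @keywords internal
NULL

.AVOGADRO <- 6.02214076e23

## coherent neutron scattering lengths, fm
.BCOH <- c(H = -3.7406, D = 6.671, C = 6.6511, N = 9.36, O = 5.803,
           P = 5.13)

## atomic masses, Da
.AMASS <- c(H = 1.00794, D = 2.014102, C = 12.0107, N = 14.0067,
            O = 15.9994, P = 30.973762)

## water at 20 C
.WATER <- list(
  H2O = list(mass = 18.01528, density = 0.99707),  # g/cm^3
  D2O = list(mass = 20.02760, density = 1.10500))

## RNA partial specific volume, cm^3/g.  0.55 reproduces published RNA SLD
## sets under the hydrogen accounting used here; configurable everywhere.
.VBAR_RNA <- 0.55

## Effective completeness of labile (N/O-bonded) hydrogen exchange with
## solvent.  Calibrated once against published SLD/match-point sets for
## helical RNA: imino and amino protons sequestered in Watson-Crick pairs
## exchange incompletely, so the effective completeness is < 1.
.FEXCH_DEFAULT <- 0.88

## Porod molecular weight defaults (nucleic acid density in kDa/A^3)
.POROD_QCUTOFF <- 0.15
.POROD_DENSITY <- 0.00054

## incoherent scattering weight of 1H relative to 2H (cross-section ratio)
.INCOH_H_OVER_D <- 40

## Displaced atomic volumes, A^3 (Fraser-style dummy atoms); riding
## hydrogens add .VDISP["H"] each.
.VDISP <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, P = 5.73)

## ---------------------------------------------------------------------------
## Ribonucleotide templates
##
## Element counts per free 5'-nucleoside monophosphate (free acid).  Hydrogens
## are split into non-exchangeable (carbon-bonded) and exchangeable (N/O-
## bonded) classes.  Chains are assembled as sum(NMP) - (n-1) H2O, then
## phosphate acidic protons are removed (phosphates are ionized at neutral
## pH), and termini are adjusted.
.NMP <- list(
  A = c(C = 10, N = 5, O = 7, P = 1, Hn = 8, He = 6),
  G = c(C = 10, N = 5, O = 8, P = 1, Hn = 7, He = 7),
  C = c(C = 9,  N = 3, O = 8, P = 1, Hn = 8, He = 6),
  U = c(C = 9,  N = 2, O = 9, P = 1, Hn = 8, He = 5))

## Internal-residue hydrogen classes (ionized phosphate, 2'-OH included in
## the exchangeable class); used by the PDB reader's implicit-hydrogen
## assignment and cross-checked in tests against the chain formula above.
.RESIDUE_H <- list(
  A = c(Hn = 8, He = 3),
  G = c(Hn = 7, He = 4),
  C = c(Hn = 8, He = 3),
  U = c(Hn = 8, He = 2))

## Riding-hydrogen counts per heavy atom of an RNA residue: list(nonexch,
## exch).  Backbone/sugar atoms are shared by all residues; base atoms are
## per residue.  Terminal 5'-OH / 3'-OH protons are added by the reader.
.RIDING_H_BACKBONE <- list(
  "P" = c(0, 0), "OP1" = c(0, 0), "OP2" = c(0, 0), "OP3" = c(0, 0),
  "O5'" = c(0, 0), "C5'" = c(2, 0), "C4'" = c(1, 0), "O4'" = c(0, 0),
  "C3'" = c(1, 0), "O3'" = c(0, 0), "C2'" = c(1, 0), "O2'" = c(0, 1),
  "C1'" = c(1, 0))

.RIDING_H_BASE <- list(
  A = list("N9" = c(0, 0), "C8" = c(1, 0), "N7" = c(0, 0), "C5" = c(0, 0),
           "C6" = c(0, 0), "N6" = c(0, 2), "N1" = c(0, 0), "C2" = c(1, 0),
           "N3" = c(0, 0), "C4" = c(0, 0)),
  G = list("N9" = c(0, 0), "C8" = c(1, 0), "N7" = c(0, 0), "C5" = c(0, 0),
           "C6" = c(0, 0), "O6" = c(0, 0), "N1" = c(0, 1), "C2" = c(0, 0),
           "N2" = c(0, 2), "N3" = c(0, 0), "C4" = c(0, 0)),
  C = list("N1" = c(0, 0), "C2" = c(0, 0), "O2" = c(0, 0), "N3" = c(0, 0),
           "C4" = c(0, 0), "N4" = c(0, 2), "C5" = c(1, 0), "C6" = c(1, 0)),
  U = list("N1" = c(0, 0), "C2" = c(0, 0), "O2" = c(0, 0), "N3" = c(0, 1),
           "C4" = c(0, 0), "O4" = c(0, 0), "C5" = c(1, 0), "C6" = c(1, 0)))

## A-form helix bead-model geometry defaults
.AHELIX_RISE <- 2.8    # A per bp
.AHELIX_DIAMETER <- 20 # A
.AHELIX_TWIST <- 32.7  # degrees per bp

## average-nucleotide ("equimolar") composition used for bead models
.BEAD_RESIDUES <- c("A", "C", "G", "U")
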