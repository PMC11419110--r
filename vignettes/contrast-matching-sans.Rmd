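---
title: "Contrast-matching SANS and SAXS analysis of deuterated RNA with nucsolv"
author: "nucsolv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-matching SANS and SAXS analysis of deuterated RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsolv)
```

# The problem

Small-angle X-ray scattering (SAXS) of an RNA:RNA complex reports only on
the overall envelope: many arrangements of the two components satisfy the
same one-dimensional profile.  Small-angle neutron scattering (SANS) breaks
this degeneracy because the neutron contrast of a molecule depends on its
isotopic, not electronic, composition.  If one RNA of a complex is
(partially) deuterated and the H2O:D2O ratio of the buffer is chosen so the
*other* RNA's scattering length density (SLD) equals that of the solvent,
the matched component becomes invisible and the measured curve reports the
bound conformation of its partner alone: contrast-matching SANS (CM-SANS).

`nucsolv` implements the computational side of such an experiment for
nucleic acids: SLD and match-point prediction from sequence and labelling,
theoretical profile simulation from coordinates with per-chain isotope
labels, and the primary one-dimensional analysis chain (Guinier,
dimensionless Kratky, Porod-volume molecular weight, logarithmic rebinning,
indirect Fourier transform to P(r), and chi-square model ranking).

# The contrast model

For a solvent with D2O volume fraction $x$, ideal-mixing gives
$\rho_{\mathrm{solv}}(x) = x\,\rho_{\mathrm{D_2O}} + (1-x)\,\rho_{\mathrm{H_2O}}$,
with the pure-water SLDs computed from coherent scattering lengths and mass
densities at 20&nbsp;°C ($6.36$ and $-0.56 \times 10^{-6}\,$Å$^{-2}$;
the package stores all SLDs in units of $10^{-6}\,$Å$^{-2}$ — beware that
publications sometimes print "Å$^{-2}$" while omitting the $10^{-6}$).

For the molecule, the atomic inventory of an RNA chain is built from its
sequence, with hydrogens split into two classes:

* **non-exchangeable** (carbon-bonded) hydrogens, per internal residue
  A:&nbsp;8, G:&nbsp;7, C:&nbsp;8, U:&nbsp;8.  A fraction $d$ of these is
  replaced by $^2$H during *in vitro* transcription with deuterated NTPs;
* **exchangeable** (N/O-bonded) hydrogens — base NH/NH$_2$ protons and
  every 2'-OH, per internal residue A:&nbsp;3, G:&nbsp;4, C:&nbsp;3,
  U:&nbsp;2, plus terminal hydroxyls — which equilibrate with the solvent
  isotope composition.

Phosphate groups are taken as ionized (no acidic protons), the state at
neutral pH; this convention fixes both the hydrogen counts and the
sequence molecular weight (the difference to the neutral free-acid mass,
about one Da per phosphate, is far below the 0.1 kDa reporting precision).

The molecule SLD is then

$$\rho_{\mathrm{mol}}(x) = \frac{\sum_{\mathrm{heavy}} b
 + n_{H}^{\mathrm{nonexch}}\,[(1-d)b_H + d\,b_D]
 + n_{H}^{\mathrm{exch}}\,[(1 - f_{\mathrm{exch}} x)b_H +
   f_{\mathrm{exch}} x\, b_D]}{V},$$

with $V = M_{\mathrm{protiated}}\bar v / N_A$ held constant under
deuteration (only mass and density change when $^1$H is replaced by
$^2$H).  Both $\rho_{\mathrm{mol}}$ and $\rho_{\mathrm{solv}}$ are affine
in $x$, so the contrast match point and the deuteration required to reach a
target match point have closed forms.

## Parameters that matter

* $\bar v$ — RNA partial specific volume, default **0.55 cm³/g**.
  Published atomic-volume sets for nucleic acids correspond to
  0.53–0.57 cm³/g; 0.55 reproduces published deuterated-RNA SLD sets under
  the hydrogen accounting above.  Configurable in every entry point.
* $f_{\mathrm{exch}}$ — effective completeness of labile-hydrogen
  exchange, default **0.88**.  A value of 1 (all N/O-bonded hydrogens
  solvent-equilibrated) makes the SLD slope versus $x$ of any chemically
  possible RNA about $1.2\times10^{-6}$ Å$^{-2}$ per unit $x$, which is
  incompatible with published SLD pairs for helical RNA (slope
  $\approx 1.0$); physically, imino and amino protons sequestered in
  Watson–Crick pairs exchange slowly and incompletely.  The default was
  calibrated once so that, with $\bar v = 0.55$, the package reproduces the
  published SLD set of a 42%-deuterated DIS hairpin (4.72 and
  5.71 $\times 10^{-6}$ Å$^{-2}$ at 0% and 100% D2O), its 90% D2O match
  point, the 65–70% match window of protiated RNA and the perdeuterated
  value 7.32; it applies to structured (helical) RNA, and should be set to
  1 for unstructured chains or fully pre-exchanged samples.
* $d$ — non-exchangeable deuteration fraction, per molecule (or per chain
  in coordinate models).

Buffer-component contributions (salts, Mg²⁺) and hydration-shell contrast
are not modelled; solvent mixing ignores the small (<0.3%) excess-volume
effect of H2O/D2O mixtures.

## The reference sequences

The package ships *synthetic stand-in* sequences
(`inst/extdata/dis_sequences_synthetic.fasta`, accessor `disSequences()`)
for the two mutant HIV-1 dimerization-initiation-site hairpins of the
reference model system: a compact hairpin whose palindromic loop is
mutated to all C (29 nt) and an elongated partner with an all-G loop, a
UCU bulge and a 16 bp extension (65 nt).  The deposited constructs' exact
sequences are not redistributed; the stand-ins follow the same
architecture and reproduce the published sequence molecular weights (9.3
and 20.8 kDa, complex 30.2 kDa), which is all that composition-level
calculations depend on.

# Theoretical profiles

`debyeIntensity()` evaluates
$I(q) = \sum_{ij} f_i f_j \,\mathrm{sinc}(q r_{ij})$ with per-particle
excess scattering lengths $f_i = b_i^{\mathrm{eff}} - \rho_{\mathrm{solv}}(x)\,v_i$.
Choices made here:

* **Implicit hydrogens.** PDB inputs need no protons: each heavy atom
  carries its riding hydrogen count from the residue templates, split into
  the same exchangeable/non-exchangeable classes, so per-chain deuteration
  labels and solvent exchange are applied exactly as in the composition
  module.  Terminal 5'-OH/3'-OH protons are added per chain.
* **Displaced volumes** come from a fixed Fraser-style dummy-atom table
  (C 16.44, N 2.49, O 9.13, P 5.73, H 5.15 Å³).  Bead particles represent
  one average nucleotide each and take $b$ and $v$ from the equimolar
  reference molecule (`averageRnaMolecule()`), which guarantees that a
  protiated bead chain has exactly zero contrast at the match point
  computed by `matchPoint()` — the simulation and the contrast calculator
  cannot drift apart.
* **No hydration shell** (CRYSOL-style shell term) and **no instrumental
  smearing**: the contrast argument operates at the bulk-solvent level,
  and desmearing is upstream of this package.  Comparisons with measured
  SANS on instruments with broad wavelength spread should expect some
  smearing-induced deviation at high $q$.
* The $q \to 0$ branch of the sinc kernel is evaluated by series, making
  $I(0) = (\sum_i f_i)^2$ exact.
* For more than ~800 particles the pair sum is accelerated by a
  distance-histogram (default bin width 0.1 Å; 0.02 Å in the accuracy
  benchmarks), accumulated in coordinate blocks so the full pair list is
  never materialised.  A bead-packed sphere is a discrete object: its
  Debye sum contains a self-term $\sum f_i^2$ that the continuum form
  factor lacks, so near the form-factor zeros the relative deviation is
  dominated by $1/n$ and pointwise 1% agreement is only meaningful where
  the form factor exceeds ~1% of $I(0)$.

`simulateCmSans()` wraps the same machinery for a labelled multi-chain
complex and returns the per-chain profiles at the identical contrast, the
masking diagnostic used throughout the in-silico validation.

# Primary analysis

**Guinier.** `guinierFit()` fits $\ln I$ vs $q^2$ by weighted least
squares.  The window is selected automatically: all contiguous windows of
at least 8 positive-intensity points are scanned, a window being
admissible when its own fitted $R_g$ keeps $q_{\max}R_g$ at or below the
ceiling (1.3 by default; 1.0 via `qRgMax` for elongated particles, which
should be used whenever Kratky or P(r) indicates a rod), when the weighted
$r^2 \ge 0.99$, and when the Wald–Wolfowitz runs statistic of the residual
signs is unsuspicious ($|z| \le 3$ — this is what stops the window from
crawling up the systematically curved part of a compact particle's curve).
Among admissible windows the longest wins; if none is admissible the best
$r^2$ window is used with a warning.  Parameter errors come from the
linear-fit covariance; on replicate synthetic data they agree with the
observed scatter within a factor of ~1.1 at realistic noise.

**Dimensionless Kratky.** $(qR_g)^2 I(q)/I(0)$ vs $qR_g$ with propagated
uncertainties.  The compact-globular guideline is the exact-Guinier value
$3/e \approx 1.104$ at $qR_g = \sqrt 3$; note that a homogeneous sphere's
true transform peaks slightly lower and earlier (≈1.03 at $qR_g$ ≈ 1.6),
so experimental "≈1.1" statements refer to the guideline, not to the
sphere's exact curve.  Rod-like particles peak well above 1.1 and decay
slowly.

**Porod volume.** $V_p = 2\pi^2 I(0)/Q$ with
$Q = \int_0^{q_c} q^2 I\,dq$ (trapezoid; the gap below the first point is
filled with the fitted Guinier model), and MW $= V_p \times$ 0.00054
kDa/Å³ with the standard nucleic-acid cutoff $q_c = 0.15$ Å$^{-1}$.  No
high-$q$ tail extension is applied, so for sharp-interface particles the
truncated invariant converges slowly and the volume is overestimated at
small $q_cR_g$ (about +50% for a homogeneous $R = 20$ Å sphere at
$q_c = 0.15$); the estimate is meaningful as the field's standard
convention, not as an unbiased volume, and the tests therefore check
convergence at larger cutoffs plus the exact scale-invariance and
monotonicity properties.

**Logarithmic rebinning.** Geometric bins with a fixed count per log
decade (SANS reductions typically use 33 or 66), inverse-variance-weighted
means and propagated sigmas; empty bins are dropped.

# P(r) inversion

`iftPr()` solves the regularized indirect Fourier transform on a uniform
101-point grid over $[0, D_{\max}]$ with endpoint zeros, a
second-difference smoothness penalty and a soft positivity penalty
(mirroring common practice for these samples; `positivity = "hard"` and
`"none"` are available).  The weight $\alpha$ is chosen by the corner
(maximum Menger curvature) of the L-curve over a 25-point log grid — a
deliberate, documented difference from GNOM's perceptual criteria, which
are not re-derived here.  Real-space $R_g$ and $I(0)$ are the second and
zeroth moments of the recovered $P(r)$.

`scanDmax()` runs the inversion over a candidate range and keeps the
*smallest* $D_{\max}$ (parsimony, reported to the nearest scanned value)
whose solution is essentially non-negative (min $P \ge -0.05$ max $P$),
decays to zero approaching $D_{\max}$ (mean $|P|$ over the last 10% of $r$
below 10% of the peak — the truncation-spike guard), and sits on the
chi-square plateau (within 50% of the floor, or 0.1 absolute when the
floor is far below 1, as with noiseless input).  On a noiseless sphere
profile this recovers $2R$ to a scan step; on low-information data the
full diagnostics table is returned and a best-effort choice is flagged.

# Model fitting

`fitScale()` minimizes $\sum [(cI_{\mathrm{calc}} + b -
I_{\mathrm{exp}})/\sigma]^2$ in closed form and reports the *reduced*
chi-square with denominator $N - p$ ($p$ = fitted parameters).  The flat
background $b$ is off by default (SAXS) and should be enabled for SANS
comparisons, where residual $^1$H incoherent background survives buffer
subtraction.  Fits are restricted to the overlap of the two $q$ grids
(linear interpolation, no extrapolation).  `rankModels()` orders
candidates by chi-square with a stable sort and reports the difference to
the best model; with noisy data the absolute value is deflated, but
relative comparisons against the same data set remain valid.

# Synthetic data

`generateShape()` produces the study geometries as bead models: uniform
spheres (random, or a deterministic lattice packing for accuracy
benchmarks), uniform rods, two-strand A-form helices (phosphate-trace
beads on a 20 Å cylinder, 2.8 Å rise, 32.7° twist, strands 150° apart and
axially staggered by one rise), hairpins (helix plus apical-loop cap) and
loop-to-loop two-hairpin kissing complexes with per-chain deuteration
labels.  The helix defaults make a 16-bp helix 44.8 Å long and put the
P(r) peak of its profile near 20 Å, the A-helix cross-section signature.

`synthProfile()` adds the two SANS noise features that matter for this
workflow: a flat incoherent background proportional to the solvent $^1$H
content (weighting $^1$H 40× relative to $^2$H, scaled by the
contrast-independent forward scattering of the protiated-buffer
condition), and heteroscedastic Gaussian noise with
$\sigma \propto \sqrt{I + \mathrm{bkg}}/\sqrt{\mathrm{exposure}}$ —
Gaussian, not Poisson, because reduced SANS data are frame-averaged.  By
default the background *mean* is subtracted again (as buffer subtraction
does), so low-%D2O conditions yield noisier rather than offset data.  A
seed is mandatory; a single RNG stream drives each call.

What the generator does **not** emulate: instrumental smearing, detector
geometry, inter-particle structure factors, conformational ensembles, and
sequence-threaded all-atom detail.  Passing the in-silico contrast-match
tests therefore demonstrates the internal consistency of the contrast
bookkeeping and analysis chain, not instrument-level realism.

# Problem sizes and numerical conventions

The validation suite uses 1200–3000-bead stochastic shapes, a
~20 000-bead lattice sphere for the Debye accuracy benchmark, 25–100
replicate noise realisations for the statistical calibrations, and 200
replicates for the reduced-chi-square check — sizes at which every
quantity under test is stable to well inside its asserted tolerance.
Other conventions: $q$ is Å$^{-1}$ everywhere (an `nm` import flag divides
by 10); intensities are arbitrary units and are never interpreted on an
absolute scale, which is why molecular weight estimation uses only the
concentration-independent Porod route; negative intensities are kept in
storage, excluded from log-space (Guinier) fits and included in
linear-space integrals.

# Known limitations

* The contrast calculator is composition-level: no per-site exchange
  kinetics, no buffer-component SLDs, no hydration shell.
* $f_{\mathrm{exch}} = 0.88$ is an effective, calibrated constant for
  helical RNA, not a measured exchange completeness.
* Porod volumes inherit the truncation bias discussed above.
* The IFT's $\alpha$ selection differs from GNOM's; recovered $D_{\max}$
  values agree with geometric truth on clean fixtures but can differ from
  GNOM's on noisy data by a few Å.
* Printed model-fit chi-squares from other software are not comparable in
  absolute terms (different background, smearing and q-range
  conventions); only relative rankings are.
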