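Package: nucsolv
Title: Contrast-Matching SANS and SAXS Analysis for Deuterated Nucleic Acids
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Solution small-angle scattering toolkit for RNA and RNA:RNA
    complexes studied by contrast-matching small-angle neutron scattering
    (CM-SANS) and SAXS. Computes neutron scattering length densities and
    contrast match points of fractionally deuterated nucleic acids from
    sequence, simulates theoretical scattering profiles from atomic or bead
    coordinates via the Debye equation with per-chain isotope labels, and
    provides the primary solution-scattering analysis chain: Guinier fitting
    with automatic range selection, dimensionless Kratky transformation,
    Porod-volume molecular weight estimation, logarithmic rebinning,
    regularized indirect Fourier transform to the pair-distance distribution
    P(r) with Dmax scanning, and chi-square model-versus-data fitting.
    Includes a synthetic-data module that generates coarse-grained helix,
    hairpin and kissing-complex bead models and SANS-like noisy profiles
    with realistic incoherent-background and counting-noise behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, StructuralPrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
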