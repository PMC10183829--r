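Package: ufmevo
Title: Comparative Phylogenomics of the UFMylation Pathway and C53 sAIM Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for comparative phylogenomic profiling of the
    UFMylation pathway and the ER-phagy receptor C53 across eukaryotes, exercised
    on synthetic proteomes. Implements iterative homology search (Smith-Waterman
    plus position-specific profile re-search with E-value calibration and a
    six-frame genome rescue stage), alignment trimming and fragment filtering,
    neighbor-joining gene trees with phylogenetic paralog screening, Dollo
    parsimony gene-loss mapping, phi-coefficient co-evolution analysis with
    Ward-D2 clustering, single- and two-group column conservation scoring,
    AIM/sAIM motif scanning and conversion, and the quantitative biophysics
    utilities the study design requires: 1:1 ligand-depletion binding isotherm
    fitting for fluorescence anisotropy, NMR chemical-shift-perturbation
    analysis, and monoisotopic remnant-adduct masses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
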