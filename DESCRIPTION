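Package: motifsym
Title: Symmetry-Aware Models of Transcription Factor Binding Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation toolkit for studying how the symmetry assumption
    affects DNA motif discovery and modeling. Defines additive binding-energy
    matrices for symmetric and asymmetric transcription factor binding sites,
    samples binding sites from the Fermi-Dirac occupancy model over the full
    sequence landscape, estimates position weight matrices under fixed,
    orientation-free (asymmetric) and reverse-complement-symmetric
    assumptions, scores motif significance with a large-deviation p-value on
    information content corrected by the number of possible alignments
    (an E-value), and quantifies model accuracy as the squared Pearson
    correlation between true and predicted log binding probabilities over
    every possible site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
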