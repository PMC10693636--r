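Package: convnovo
Title: De Novo Peptide Sequencing from Tandem Mass Spectra with Dilated
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers peptide sequences directly from higher-energy collisional
    dissociation (HCD) tandem mass spectra without a sequence database. A
    spectrum is binned into a fixed-length intensity vector and passed through
    a stack of dilated temporal-convolution blocks whose outputs are fused
    into a 32-position by 23-class probability matrix, from which the peptide
    is read off greedily with a precursor-mass rescue step and scored by the
    product of its per-residue probabilities. Includes a synthetic HCD
    spectrum simulator, MGF input/output, peptide-disjoint data splitting,
    training with a masked cross-entropy plus mass-error loss and auxiliary
    multitask heads, and the standard evaluation metrics (positional and
    peptide-level accuracy with Leu/Ile equivalence, precursor ppm filtering,
    precision-coverage curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
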