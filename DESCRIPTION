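Package: secmature
Title: Classification of Bacterial Sec-Secretory Proteins from Mature Domain Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates bacterial Sec-dependent secretory protein sequences
    from cytoplasmic ones using features computed from fixed-length N-terminal
    sequence windows, including mature domains with the signal peptide removed.
    Implements position-specific binary encodings under alternative residue
    groupings, k-mer fractions, hydrophobicity-customized pseudo-amino-acid
    composition, and folding-component energies derived from the
    eigendecomposition of a pairwise interaction-energy predictor matrix.
    Model selection runs a configuration grid of feature-selection and
    classifier hyper-parameters under stratified K-fold cross-validation with
    bootstrap bias-corrected performance estimation. Trained linear models can
    be rendered as sequence-logo-like weight stacks, and a combined
    signal-peptide plus mature-domain decision assigns cytoplasmic, mature,
    secretory-preprotein or non-secretory verdicts. A synthetic-data generator
    produces labeled FASTA/TSV fixtures with planted class differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    e1071,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
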