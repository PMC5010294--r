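Package: PSEE
Title: Position Specific Estimated Energy for Protein Disorder Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the position specific estimated energy (PSEE) of
    protein residues from sequence and predicted solvent accessibility
    alone, by weighting pairwise residue contact potentials with
    proportional burial over a sliding sequence neighbourhood. Provides
    the packaged contact-energy and accessible-surface-area reference
    tables, order/disorder threshold analysis with contact-radius tuning,
    windowed feature assembly and an RBF-kernel probabilistic disorder
    classifier with Youden-J threshold optimisation, confusion-matrix and
    ROC/precision-recall evaluation, tie-aware competition ranking of
    predictors, and a synthetic labelled-dataset generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
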