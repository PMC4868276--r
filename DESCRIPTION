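Package: acetylsite
Title: Species-Specific Lysine Acetylation Site Prediction from
    Sliding-Window Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts lysine (K) acetylation sites in protein sequences
    with a radial-basis-function support vector machine trained on a large
    set of sliding-window features.  Fourteen feature subtypes are encoded
    from the sequence itself (terminal location, position-weight amino-acid
    composition, grouped-weight binary projections, k-spaced residue-pair
    composition, nearest-neighbour scores under a BLOSUM62 distance,
    auto-cross covariance, parallel-correlation pseudo amino-acid
    composition, physicochemical property scales) and from per-residue
    profiles produced by external predictors (secondary structure, relative
    solvent accessibility and backbone torsions, disorder, half-sphere
    exposure, PSI-BLAST and HMM-profile scoring matrices with an entropy
    conservation score).  Features are ranked per subtype by Pearson
    correlation with the class label and selected by a greedy stepwise pass
    under cross-validated SVM accuracy.  Includes parsers for the external
    profile formats, standard binary-classification metrics with ROC/AUC,
    and a synthetic data generator so the full pipeline can be exercised
    without third-party tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
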