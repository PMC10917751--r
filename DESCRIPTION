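Package: pepXplain
Title: Local Attribution Explanations for Peptide-MHC Class I Binding
    Predictors and Their Quality Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-position attribution explanations (exact Shapley
    values, Kernel-SHAP, and LIME) for black-box peptide-MHC class I binding
    predictors over fixed-length peptides, and evaluates explanation quality
    along three axes: validity against per-position alanine-scan binding
    free-energy differences (ddG), consistency across comparably performing
    predictors with a permutation baseline and Kruskal-Wallis testing, and
    stability across similar peptides grouped by Gibbs-sampling motif
    clustering with a Kullback-Leibler distance objective. Includes
    PSSM-based surrogate predictors, benchmark-style dataset curation,
    per-allele AUROC/AUPRC benchmarking, and a synthetic study generator so
    the full pipeline is testable without trained deep-learning models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    withr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Classification, Proteomics, ImmunoOncology,
    MachineLearning
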