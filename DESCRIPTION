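Package: singulOR
Title: Singular Olfactory Receptor Expression Analysis for Single-Cell and
    Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify singular olfactory receptor (OR) choice in
    developing olfactory sensory neurons from single-nucleus and imaging-based
    spatial transcriptomics. Implements a per-cell OR dominance score
    contrasting the top- and second-most expressed receptor, high-dominance
    classification and binning, contingency statistics (Pearson chi-square,
    Cramer's V with bootstrap confidence intervals, per-bin post-hoc tests
    with Benjamini-Hochberg correction) linking cell identity to OR-count
    categories, sex- and erythroid-score based detection of maternal blood
    contamination, donor-level pseudobulk cell-type composition tests, and
    spatial axis binning of MERFISH-style segmented-cell tables. A synthetic
    cohort generator with recorded ground truth supports end-to-end testing
    and parameter recovery without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: SingleCell, Transcriptomics, Spatial, QualityControl, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
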