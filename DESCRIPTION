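Package: fiamrm
Title: Automated Dilute-and-Shoot FIA-MRM Method Assembly and QC Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds organism-specific multiple-reaction-monitoring (MRM)
    screening methods for chromatography-free dilute-and-shoot flow-injection
    analysis (DS-FIA) from genome-scale metabolite lists, predicted pKa values
    and predicted MS/MS spectra. Covers identifier-chain resolution
    (KEGG, PubChem, ChEMBL) behind a pluggable fetcher contract, pKa-based
    acid/base/amphoteric classification and electrospray polarity allocation,
    parsing and validation of predicted fragment spectra (recall, precision,
    weighted variants and Jaccard score), isobaric-convolution-aware
    transition selection, balanced distribution into instrument-ready method
    packages, and injection-batch design. A downstream statistics pipeline
    provides signal-to-noise filtering, QC-based LOESS drift correction, QC
    acceptance, imputation, range scaling, PCA, multiclass PLS-DA with
    stratified double cross-validation, bootstrap confidence intervals for
    coefficients and VIP scores, Kruskal-Wallis testing and variable
    selection. Synthetic-fixture generators emulate every input so the whole
    workflow runs without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
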