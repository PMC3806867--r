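Package: screen3D
Title: Analysis of High-Throughput Drug Screens Across 2D and 3D Cell
    Culture Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for 384-well luminescence (CellTiter-Glo) drug
    screens run in parallel across monolayer (2D) and three-dimensional
    (Matrigel, polyHEMA) culture models. Implements robust loess
    spatial-bias correction with negative-control log2 normalization
    ("loess-log"), least-squares replicate aggregation, rank-product
    hit calling of 3D-versus-2D drug responses with permutation-based
    false-positive rates, percent-of-lowest-concentration dose-response
    summaries with an activity filter and concentration-binned
    cross-model comparison, and multiple linear regression
    classification of drug-sensitized culture models. Downstream
    expression utilities compare culture models to xenografts by
    fold-change counting, Venn partitioning and bootstrap-supported
    correlation clustering. A synthetic screen generator with Hill
    dose-response truth, smooth spatial plate artifacts and
    multiplicative lognormal noise supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Normalization, Regression,
    GeneExpression, Clustering
RoxygenNote: 7.3.3
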