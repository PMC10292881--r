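Package: multiclock
Title: Multimodal Transformer Aging Clock with Transfer Learning and
    Shapley-Based Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a tabular-transformer age regressor on stacked DNA
    methylation (TSS200 promoter beta values) and gene expression
    (normalized log-TPM) cohorts, converts it into case-control
    classifiers by frozen-backbone transfer learning, prioritizes genes
    by permutation-sampling Shapley attribution, and tests ranked gene
    lists for gene-set over-representation with an Enrichr-style
    combined score. Includes a synthetic multimodal cohort generator
    with planted age and disease signals, preprocessing (TSS200
    aggregation, empirical-Bayes batch correction, quantile
    normalization, stratified splitting), and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
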