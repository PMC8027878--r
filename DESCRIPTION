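Package: plasmaseek
Title: Plasma-Proteome Biomarker Mining from Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines plasma-detectable candidate biomarkers from bulk tumor
    RNA-seq cohorts. Screens genes for tumor-versus-normal differential
    expression with rank-based (Mann-Whitney U) tests restricted to a
    plasma-proteome gene panel, classifies stage-wise expression patterns
    (leading, stage-specific, progressive), builds paired similarity and
    dissimilarity weighted co-expression networks with soft-threshold
    scale-free fitting, ranks gene importance by the ratio of closeness
    centralities (RCC) between the two network layers, and evaluates
    biomarker panels with repeated cross-validated linear support-vector
    classification (mean ROC/AUC against a random-gene baseline). Ships a
    synthetic-cohort generator with planted effect classes and correlated
    gene modules so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
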