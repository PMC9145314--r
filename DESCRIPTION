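Package: npinflam
Title: Dose-Response Benchmark-Dose Modelling and Transcriptomics for
    Nanoparticle Inflammasome Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro nanoparticle inflammasome
    screening with differentiated THP-1 cells. Fits nested exponential and
    Hill dose-response families by maximum likelihood under a log-normal
    error model, selects family members by likelihood-ratio testing with a
    saturated-model goodness-of-fit check, and derives benchmark doses
    (BMD) with profile-likelihood confidence bounds and geometric model
    averaging. Also provides deterministic plate-assay arithmetic (WST-1
    viability normalization, five-parameter logistic ELISA calibration and
    inversion, endotoxin threshold classification, dose-metric conversion,
    particle surface-to-volume geometry), a one-colour microarray pipeline
    (feature reliability filtering, log2 quantile normalization,
    gene-symbol collapse, per-comparison t-tests, DEG union with an
    expected-false-positive FDR estimate, PCA, clustered log2 fold-change
    heatmaps), gene set enrichment analysis with a weighted running-sum
    statistic and a gene-label permutation null, and a seeded
    synthetic-data generator that emulates every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    pheatmap,
    optparse
Config/testthat/edition: 3
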