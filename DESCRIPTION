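Package: difatten
Title: Genotype-Dependent Treatment-Response Gene Selection via DIF
    Attenuation Scores
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Selection of genes whose surgical (DMM) osteoarthritis response
    is attenuated by a gene knockout, from bulk RNA-seq TPM matrices with one
    pooled sample per genotype x condition x timepoint cell. Implements TPM
    expression filtering, per-genotype log2(DMM/sham) contrasts, the DIF
    attenuation score with a lower-quartile threshold, consistent selection
    across two timepoints, hypergeometric overlap significance, ortholog
    mapping and hallmark gene-set hypergeometric enrichment with
    Benjamini-Hochberg FDR, together with a seeded synthetic-data generator
    that plants ground-truth attenuated genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    methods,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
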