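Package: mmra
Title: MicroRNA Master Regulator Analysis for Transcriptional Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate driver microRNAs of transcriptional subtypes
    from paired mRNA-microRNA expression data by serially combining four
    analysis stages: subtype-core differential expression with a bootstrap
    Kolmogorov-Smirnov test and permutation-estimated FDR; hypergeometric
    enrichment of predicted microRNA targets in subtype gene signatures with
    randomized-set FDR threshold selection; single-hub mutual-information
    regulons with bootstrap consensus and master regulator analysis against a
    null model of non-differential microRNAs; and stepwise linear regression
    attribution of signature-gene expression to microRNAs. Includes a
    synthetic paired-dataset generator with planted driver microRNAs for
    end-to-end validation, and downstream procedures for cell-line
    consolidation, silencing-response differential expression, and core
    target identification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    limma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
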