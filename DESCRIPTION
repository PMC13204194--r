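Package: mircargo
Title: Integrative Analysis of Extracellular-Vesicle miRNA Cargo and
    Recipient-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying how extracellular
    vesicle (EV) shuttled microRNAs reshape the transcriptome of recipient
    cells. Implements abundance filtering of TPM matrices, small-sample
    differential expression with up/down classification, transcript-to-gene
    collapsing into a ranked list, pre-ranked gene-set enrichment with a
    permutation null, hypergeometric over-representation analysis,
    spike-in-normalised delta-delta-Ct quantification of qPCR miRNA cards
    with expression-calling rules, multi-database consensus miRNA-target
    integration against downregulated genes, pathway-convergence analysis,
    and Kaplan-Meier survival analysis with scan-mode cutoff selection.
    A synthetic-data module generates every pipeline input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
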