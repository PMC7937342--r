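Package: spiroseq
Title: Symbiont-Mediated Protection Transcriptomics: Depurination Calling,
    Interaction Set Logic and RNA-Seq Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for tripartite host-symbiont-parasitoid RNA-seq
    studies. Detects ribosome-inactivating-protein (RIP) depurination at the
    28S rRNA sarcin-ricin loop from sequencing reads via motif-anchored base
    counting with replicate quality control and a separation-robust penalized
    binomial GLM; classifies interaction-responsive genes with
    direction-stratified Venn set logic over three differential-expression
    contrasts, including "restored" and symbiont-boosted expression patterns;
    computes closed-form RNA-seq power and required sample sizes; performs
    efficiency-corrected delta-Ct qPCR arithmetic; and ships a synthetic-data
    generator (stranded depurinated reads and factorial negative-binomial
    count matrices with planted gene classes) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    MASS,
    Biostrings,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
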