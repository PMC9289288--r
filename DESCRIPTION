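Package: gravirebound
Title: Layered RNA-Seq Dynamics of Rapid Transcriptional Rebound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rapid transcriptional dynamics in
    short time-course RNA-seq experiments, built around spliced/unspliced
    read-layer quantification. Provides gene-model and cytoband indexing,
    a mechanistic two-stage kinetic simulator (transcription, splicing,
    degradation with step perturbations and rebound), splice-aware read
    classification into spliced/unspliced/ambiguous count layers,
    negative-binomial differential expression with shared size factors
    across layers, temporal rebound and transition classification,
    observed-versus-expected tests of regulated genes over chromosomes and
    cytobands, differential exon usage with transcript-biotype association,
    the protein-coding counts ratio (PCCR) statistic, and Fisher plus
    preranked gene-set enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    MASS,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    fgsea,
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
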