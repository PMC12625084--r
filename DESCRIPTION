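Package: genefamr
Title: Gene Family Characterization Pipelines for Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for multi-stage characterization of
    plant gene families: domain-based family census with protein
    physicochemical properties (molecular weight, isoelectric point,
    PROSITE-style site counts), distance-based ortholog nomenclature with
    neighbor-joining trees, expression-expression Pearson correlation against
    flowering-gene panels, trait-specific allele mining from grouped
    resequencing variants with coding-consequence annotation, promoter
    motif-set enrichment against a genome-wide log-normal background,
    MCScanX-style collinear block chaining with syntenic gene networks, and
    QTL/QTN proximity scans. Includes a fully deterministic synthetic-data
    generator that plants ground truth (family members, trait-specific
    variants, promoter motifs, duplicated segments, expression modules) so
    every stage is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    igraph,
    yaml,
    jsonlite,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
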