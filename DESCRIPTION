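Package: crypticex
Title: Cryptic-Exon Discovery and Recessive Variant Association for Rare
    Disease Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for identifying deep-intronic variants
    that create cryptic (pseudo-)exons in autosomal recessive disease, modelled
    on the genetics of equine juvenile spinocerebellar ataxia (EJSCA) in
    Quarter Horses. Provides recessive segregation filtering and allelic Fisher
    exact association over multi-sample VCFs, cryptic-exon calling from spliced
    read block evidence, greedy identity-threshold clustering of long-read
    amplicons with consensus building and isoform classification, in-frame
    translation with premature termination codon detection, HGVS intronic
    nomenclature, and population allele-frequency estimation from carrier
    screening panels. A synthetic-data generator plants a fully recorded truth
    (locus, cohort, spliced reads, amplicons, genotyping panel) so the whole
    chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
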