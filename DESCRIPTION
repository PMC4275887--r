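Package: vellum
Title: Ancient DNA Screening and Genetic Affinity Analysis for Parchment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating and analysing shotgun ancient-DNA
    sequencing of parchment and other historical animal-skin artefacts:
    multi-genome read screening and species identification with a
    desk-scale ungapped aligner, endogenous-DNA quantification through a
    mapping-quality/duplicate/contaminant/uniqueness filter chain,
    mitochondrial consensus building with a conservative contamination
    statistic and neighbour-joining haplogroup placement, pseudo-haploid
    SNP genotyping with breed-level allele-sharing summaries, collagen
    peptide-mass fingerprinting (ZooMS) species calls, and a
    synthetic-data generator for damaged short-read libraries,
    mitochondrial haplotype mixtures and structured SNP panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
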