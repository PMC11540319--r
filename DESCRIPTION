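Package: nrhap
Title: Haplogroup Calling and Association Testing for Nonrecombinant Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for Y and mitochondrial (MT) chromosome haplotypes
    in outbred heterogeneous stock (HS) rat populations genotyped at low coverage.
    Provides an ordered genotype filter cascade (imputation INFO score, minor
    allele frequency, per-variant and per-sample missingness), hemizygous
    heterozygote masking, majority-allele haplogroup assignment with consensus
    haplotypes and founder-strain matching, neighbor-joining phylogenies on
    pairwise Hamming distances that ignore missingness, mixed-linear-model
    phenome-wide association with an autosomal genetic relationship matrix and
    REML variance components, trimmed-mean-of-M-values normalization with
    Mann-Whitney differential expression by haplogroup, sex-stratified X-SNP
    linear scans, and a synthetic-data generator that emulates founder panels,
    low-coverage observation noise, polygenic phenotypes, and negative-binomial
    expression counts with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    edgeR,
    yaml,
    jsonlite
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
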