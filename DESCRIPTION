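Package: napusdiv
Title: Population Genomics of Sparse Sequence-Based Genotyping Panels
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-genomic analysis of sparse,
    high-missingness SNP panels such as those produced by restriction-site
    anchored sequence-based genotyping of the allotetraploid crop Brassica
    napus. Covers the raw-variant filter cascade (biallelic/fixed-alternate
    removal, genotype depth masking, allelic-imbalance recoding, per-sample
    locus mismatch masking, site and sample call-rate filters), probabilistic
    PCA on incomplete genotype matrices, Hudson Fst as a ratio of averages
    with inbreeding-deflated chromosome counts and dual ascertainment,
    hypergeometric projection of the folded site-frequency spectrum with
    nucleotide diversity and Tajima's D, minor-allele sharing partitions with
    size-matched downsampling, matched-composition gene-set permutation tests,
    inversion-signature region scanning via per-region PCA banding, and
    neighbor-joining phylogenies from weighted genotype distances with
    midpoint rooting and bootstrap supports. A synthetic-data generator with
    tunable differentiation (Balding-Nichols), selfing-level inbreeding,
    depth-coupled missingness and segregating inversion haplotypes makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
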