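Package: soypopgen
Title: Population Genomics and Mixed-Model Association Analysis for
    Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the population-genomic analysis of structured
    resequencing panels such as soybean mini-core collections: biallelic
    genotype panels from VCF with minor-allele-frequency and missingness
    filters, windowed nucleotide diversity, Weir-Cockerham F_ST and
    linkage-disequilibrium r^2, private/shared variant classification,
    Jukes-Cantor distances with neighbour-joining trees and classical
    multidimensional scaling, EMMAX-style linear mixed-model genome-wide
    association scans with Wald tests and Benjamini-Hochberg FDR control,
    codon-aware variant-effect annotation against gene models, structural
    variant summaries, and CNV-seq style windowed read-depth ratio tests.
    Includes a synthetic-data generator (Balding-Nichols structured
    genotypes, quantitative traits with known heritability, SV call sets,
    CNV read counts and toy gene models) so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
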