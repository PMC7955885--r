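Package: napusweep
Title: Selective-Sweep Scans, LTR-RT Dating, Centromere Detection and NLR
    Pairing for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidyverse-native toolkit for the bespoke population and repeat
    genomics computations used in chromosome-scale Brassica napus genome
    studies: windowed nucleotide diversity and Weir-Cockerham FST scans with
    joint empirical-quantile sweep calling between ecotype groups, SNP effect
    classification and summarisation against a GFF3 annotation, LTR
    retrotransposon insertion-age dating from terminal-repeat divergence
    (T = K/2r) with centromeric-enrichment testing, centromeric satellite
    monomer and tandem-array detection, and NB-ARC/NLR locus reconciliation
    with head-to-head pair calling. A synthetic-data module generates VCF,
    FASTA, GFF3 and BED inputs with planted truth so every stage is testable
    without large resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    methods,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
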