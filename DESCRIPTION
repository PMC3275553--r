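Package: mos1tk
Title: Simulation and Analysis of Mos1 Transposon Insertion Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for transposon insertion-site collections
    of the kind produced for the C. elegans Mos1 mutant resource. Simulates
    insertion libraries on synthetic genomes (TA-dinucleotide target model,
    plate-structured strain production, resident-insertion and
    cross-contamination artifacts), models the inverse-PCR recovery of
    insertion flanks (MboI/HaeIII digestion, amplicon size filters, band
    selection), maps flank reads back to the genome with ambiguity
    rejection and TA snapping, collapses coordinate-redundant alleles with
    a 10-bp single-linkage rule, and computes genome-wide distribution
    statistics (chromosome proportionality, nearest-neighbour gaps, CDS
    context fractions, exact binomial gene-set enrichment), 1.5-kb
    MosTIC-reachability coverage tables, and gene-proximity allele queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
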