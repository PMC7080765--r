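Package: chipsmith
Title: Genic SNP Chip Design and Genotype Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Re-usable toolkit for designing genic SNP genotyping arrays and
    analysing the resulting chip genotype calls, modelled on the design
    pipelines behind single-copy-gene Axiom arrays for crop species. Covers
    similarity-based gene categorisation (single-copy, conserved single-copy,
    agronomic-gene, disease-resistance and multi-copy classes), flanked
    reference-sequence extraction from genome FASTA/GFF3, pileup-summary SNP
    filtering and exon/intron/UTR annotation, Axiom-style 72-bp probe plex
    construction with interfering-SNP exclusion and a documented surrogate
    designability score, genotype-matrix quality control (call rate,
    heterozygosity, concordance, minor allele frequency, recombinant-inbred
    segregation-distortion filtering), identity-by-state distances with
    neighbor-joining trees, unlinked-SNP subset selection with STRUCTURE and
    PLINK export, per-gene haplotype tables with Nei haplotype diversity and
    median-joining haplotype networks, and seeded synthetic-fixture
    generators so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
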