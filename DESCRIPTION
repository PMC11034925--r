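Package: cnevol
Title: Conserved Noncoding Element Detection and Evolution in Teleost Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying the evolution of conserved
    noncoding elements (CNEs) across fish genomes. Implements pairwise
    seed-and-extend genome alignment with collinear chaining and reference-side
    netting, sliding-window CNE detection with exon/repeat filtering and a
    repeat copy-number cutoff, Karlin-Altschul E-value based cross-genome
    presence search, ancestral-repertoire reconstruction with origin dating
    against outgroups, 500 kb genomic-zone profiling, orthology-guided
    synteny-based gene-target association with a bootstrap resampling null,
    whole-genome-duplication paralogy clustering, CNE-based phylogenomics
    (supermatrix + neighbor joining), and consensus-motif scanning. Ships a
    genome-evolution simulator that plants CNEs of three evolutionary ages on a
    known species tree (with a lineage-specific whole-genome duplication,
    element losses, rearrangements and repeats) so that every stage can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
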