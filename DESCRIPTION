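Package: skewscape
Title: Comparative Architecture of Circular Bacterial Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative genome-architecture analysis of circular
    bacterial chromosomes, centred on gene transfer agent (GTA) gene clusters
    and core genes. Reads and rotates closed chromosomes with their gene
    annotations; computes GC-content and GC-skew tracks, cumulative and
    cohort-averaged skew profiles, and calls local GC-skew peaks by sliding
    quantiles; classifies genes by replichore, leading/lagging strand and
    typical-skew versus potential-inversion categories; compares codon usage
    between peak and background gene sets including matched-codon and
    rank-correlation analyses; calls core gene families from orthologue
    presence matrices and measures their enrichment in skew peaks; classifies
    gene distance to long repeats; and profiles DNA methylation motif (GANTC)
    density along origin- or gene-anchored chromosomes. A seedable synthetic
    genome generator with planted ground truth makes every pipeline stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
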