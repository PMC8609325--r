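Package: microchrom
Title: Microchromosome Conservation from Alignment Chains and Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative-genomics toolkit for studying the evolutionary fate of
    microchromosomes. Reads UCSC pairwise alignment chains, reduces them to
    reciprocal-best syntenic blocks, classifies chromosomes as macro or micro by
    clade-specific size thresholds, quantifies micro-to-micro homology between
    species, calls chromosome fusion and fission events from syntenic-block
    composition, partitions a derived genome into four ancestral-state region
    classes, and computes per-class GC content and distance-dependent Hi-C
    contact probabilities P(s) from binned GInteractions matrices. A seeded
    karyotype-evolution simulator generates every pipeline input together with
    a ground-truth event log, so the whole analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
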