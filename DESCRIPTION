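Package: gc3sig
Title: Wobble-Position GC Composition, Genome Signatures and GC3 Gene Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-gene codon-position composition statistics (GC1, GC2, GC3,
    GC12, CG3 skew, CG/GC dinucleotide ratio and 5'-to-3' sliding-window
    gradients), dinucleotide and trinucleotide genome-signature statistics
    (relative abundances including position-specific and conditional
    third-position variants), kernel-density based high/low GC3 class
    assignment with valley thresholding and spatial analyses (adjacent-gene
    correlation, clump detection), and a battery of covariate analyses
    relating GC3 to expression variability, TATA boxes, introns, SNP density
    and codon-usage principal components. Ships a seeded synthetic-data
    generator that plants a two-component GC3 mixture and every modelled
    association, so the whole pipeline can be exercised and validated
    end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
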