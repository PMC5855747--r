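Package: plastomekit
Title: Comparative Analysis of Chloroplast Genome Structure, Repeats and
    Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of annotated chloroplast
    (plastid) genomes: detection of the inverted-repeat pair and derivation
    of the quadripartite partition (LSC, IRa, SSC, IRb), inspection of
    expansion and contraction at the four single-copy/IR junctions,
    microsatellite (SSR) scanning under motif-length-specific copy-number
    cutoffs, detection of long forward/reverse/complement/palindromic
    repeats, exon/intron accounting and cross-taxon intron-loss calls with
    in-silico PCR verification, per-gene alignment variability statistics
    including Fitch parsimony consistency and retention indices, k-mer
    dot-plot comparison with inversion detection, and a ground-truth
    synthetic plastome generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
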