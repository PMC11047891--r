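Package: L1PD
Title: LINE-1 Detection by Seed-and-Pattern-Match
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects full-length LINE-1 (L1) retrotransposons in assembled
    genomes with a seed-and-pattern-match strategy: a fixed set of conserved
    k-mer probes derived from aligned ORF1/ORF2 sequences is mapped against a
    genome under a maximum edit distance, and ordered constellations of probe
    hits whose spacing is consistent with the probe offsets are chained into
    L1 calls with boundaries extrapolated from component-length modes.
    Includes the probe-generation pipeline from per-ORF multiple sequence
    alignments, SAM import of pre-computed probe mappings, GFF3 output, a
    precision/recall/F1 parameter-sweep harness, and a seeded simulator of
    genomes with planted L1 copies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    Rcpp,
    Rsamtools,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
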