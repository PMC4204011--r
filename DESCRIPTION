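Package: cgikit
Title: Design, Scanning and Methylation Analysis of CpG-Island-Like DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how DNA base composition shapes CpG-island
    (CGI) chromatin. Generates random DNA sequences under exact joint
    constraints on length, G+C content and CpG count (artificial CGIs);
    computes composition metrics (G+C fraction, CpG density,
    observed/expected CpG ratio) and sliding-window profiles; tiles genomes
    into fixed windows and detects blocks of atypical composition
    (A+T-rich/CpG-rich or G+C-rich/CpG-poor domains); calls per-CpG
    methylation from bisulfite clone sequences with conversion QC; and
    relates interval features to chromatin signal via quartile binning,
    overlap fractions and rank correlation. Includes seeded generators of
    synthetic genomes, bisulfite clones and feature-signal interval sets
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
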