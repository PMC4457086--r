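Package: rnetseq
Title: Pause-Site, Translocation-State and Transcription-Error Analysis for
    RNase-Footprinted Nascent Transcript Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing RNase-footprinted native elongating
    transcript sequencing (RNET-seq) of bacterial RNA polymerase.
    Calls strand-specific pause sites from 3'-end pileups using the
    P(phi, delta) statistic, infers translocation states from
    protected-fragment lengths (14 nt post-translocated, 15 nt
    pre-translocated, >= 16 nt backtracked), builds pause-motif
    frequency matrices with information content, profiles per-position
    transcription-error rates (all 12 substitution types) from
    CIGAR/MD alignments, and computes gene- and region-level pausing
    metrics. Includes a synthetic elongation-complex read simulator
    with planted pause motifs, translocation-state footprints and
    3'-end misincorporations for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
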