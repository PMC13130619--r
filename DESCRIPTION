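Package: orfrescue
Title: Triage of Out-of-Frame Kinase Gene Fusions via Alternative Translation Starts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tertiary-analysis toolkit for deciding whether a chimeric
    transcript called by RNA-seq fusion detectors could still produce a
    functional kinase despite an out-of-frame junction. Reconstructs the
    fusion cDNA from a genome and annotation, classifies the junction
    reading frame, scans the 3' portion for alternative (downstream) ATG
    start codons that restore the native kinase open reading frame, tests
    for 5'/3' exon-level expression imbalance with an exact tie-aware
    Wilcoxon rank-sum test, and evaluates a five-criterion triage workflow
    (druggable 3' kinase, in-strand orientation, out-of-frame prediction,
    kinase-domain preservation, dual-gene expression imbalance). Parses
    Arriba-, FusionCatcher- and STAR-Fusion-style call tables and
    harmonizes them into cross-caller concordance groups. Ships a seeded
    synthetic fixture generator (toy references, engineered fusions,
    negative-binomial exon counts) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
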