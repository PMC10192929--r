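Package: nucshield
Title: Radial 3D Genome Organization of UV Damage and Excision Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to relate the radial organization of the nucleus to
    UV-induced DNA damage (Damage-seq) and nucleotide excision repair
    (XR-seq). Builds a bead-per-domain 3D nucleus model from contact
    domains and significant Hi-C interactions via interaction-constrained
    Monte Carlo, partitions beads into concentric 1-micrometre radial
    shells, and computes per-bead RPKM, observed/expected fold change
    against nucleotide-frequency-matched simulated reads, and
    double-normalized repair statistics per shell, with Welch's t-tests
    between the central shell and every other shell. Includes a
    frequency-matched read simulator with closed-loop feedback, lesion
    window extraction for Damage-seq reads, genic/intergenic and
    replication-timing stratification, and a synthetic-data generator
    with plantable radial structure so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
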