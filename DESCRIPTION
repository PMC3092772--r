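Package: targetasm
Title: Targeted Localized Assembly of Short Sequencing Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interrogates large next-generation sequencing read sets for
    user-specified sequence variants by localized de novo assembly. Every
    k-length word (default 15) is extracted from both strands of each target
    sequence and held in a hash index; a read is recruited if and only if its
    first k bases exactly match an indexed word. Recruited reads are placed on
    the target coordinate axis under a strict perfect-agreement rule, per-base
    counts are tallied within and beyond the target, and the consensus is
    extended bidirectionally into flanking sequence under coverage and
    base-ratio thresholds. Includes target-design helpers for SNV allele
    pairs, ambiguous-last-base fusion probes and breakpoint junction targets,
    variant-support reporting, a seeded read simulator with implanted ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
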