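Package: sysindel
Title: Systematic Homopolymer Indel Profiling for Hybrid Long/Short-Read Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes systematic single-base indel errors that long-read
    (single-molecule) sequencing introduces at G/C homopolymer tracts of
    high-GC bacterial genomes, by comparing long-read and accurate short-read
    pileups over a draft assembly. Provides a synthetic multi-replicon genome
    and read simulator with planted truth sets, pileup-based consensus indel
    calling, homopolymer context statistics, coding-frame impact (ORF
    fragmentation) analysis, a position-weight-matrix flanking-motif
    permutation test, and read-depth based replicon copy-number ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
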