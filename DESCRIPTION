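Package: sexlinkr
Title: Sex-Linked Contig Classification from Male and Female Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies X- and Y-linked contigs in a genome assembly from
    whole-genome sequencing depth of male and female samples. Windowed read
    depth is corrected for GC bias with a LOESS fit, converted to copy-number
    estimates (diploid = 2), combined across replicates, and classified with
    explicit male/female copy-number rules (Y: single copy in males, absent
    in females; X: twofold higher copy number in females). Also provides a
    k-mer based purge of allelic (haplotig) contigs that keeps the longer
    contig of each allelic pair, standard assembly summary statistics
    (N50/L50, GC content), and a synthetic genome and coverage-track
    simulator with GC bias and Poisson or negative-binomial noise so the
    whole pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
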