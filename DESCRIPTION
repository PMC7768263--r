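Package: rapidfoot
Title: RNA Polymerase DamID Footprinting from Long-Read Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for RNA polymerase DamID (RAPID) analysis: indexing GATC
    motifs and restriction fragments in a genome, validating aligned long-read
    amplicons whose ends must fall at GATC sites, normalizing fusion versus
    Dam-only fragment counts into log2 polymerase-occupancy tracks, calling
    significantly footprinted genes with a permutation null and
    Benjamini-Hochberg FDR, tissue gene-set algebra and marker-candidate
    refinement, metagene and ranked-bin profiling, bootstrap true-positive-rate
    estimation, and a synthetic-data generator that emulates the full assay so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
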