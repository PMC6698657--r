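Package: mhjunction
Title: Microhomology Analysis at CRISPR-Induced Deletion Breakpoint Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing larger-than-expected deletions arising from
    CRISPR/Cas9 genome editing. Scores exact microhomologies abutting deletion
    breakpoint junctions, compares observed microhomology length distributions
    against an analytic chance expectation and a simulated random-genomic
    background, counts bypassed alternative microhomologies inside deleted
    sequences, tests for GC bias in microhomology composition, quantifies
    insertion fractions in short-amplicon allele tables, and fits a linear
    model of deletion frequency on log-proximity to sgRNA cut sites and
    per-sample cutting efficiency from droplet digital PCR measurements.
    Includes seeded generators for synthetic genomes, repair-outcome allele
    sets with controllable microhomology-mediated end joining structure, and
    ddPCR-style frequency tables, so the full pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
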