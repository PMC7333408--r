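Package: blockprimr
Title: Blocking-Primer Design and In Silico PCR for Host-DNA Depletion in
    Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs host-blocking primers for amplicon metabarcoding and
    evaluates primer sets in silico. Provides IUPAC-aware degenerate primer
    matching with mismatch tolerance on both strands, amplicon extraction
    from taxonomy-annotated reference databases (Silva-style FASTA headers),
    enumeration and selection of blocking-primer candidates from the 3'
    region of host amplicons under length, reverse-primer-overlap and
    melting-temperature constraints, per-taxon amplification/blocking
    profiles, and a seeded simulator of reference databases with planted
    primer sites for validation. Ships a command-line interface wrapping
    the amplify, design, profile and simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
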