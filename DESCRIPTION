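Package: codonflux
Title: Codon Usage, Ribosome Flux and Codon Decoding Kinetics from
    Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("codonflux", "developers", email = "codonflux@example.org",
           role = c("aut", "cre"))
Description: Tools linking codon usage bias, coding-sequence length,
    ribosome flux and codon decoding kinetics in ribosome-profiling,
    RNA-seq and proteomics data. Computes codon-usage indices (CAI, CBI,
    tAI), performs synonymous codon optimization, turns A-site-assigned
    footprints into codon-level occupancy, gene-level TPM and ribosome
    density, and relative codon decoding times (overall and stratified by
    CDS length); provides genome-scale scanning-window correlation
    analytics, differential ribosome-density classification, and a
    fully seeded synthetic-data generator that plants the statistical
    structure the analyses assume, so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
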