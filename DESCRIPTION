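Package: polfid
Title: Forward Mutation Assay Analysis for DNA Polymerase Fidelity
Version: 0.1.0
Authors@R:
    person("Maintainer", "Polfid", email = "polfid@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for forward-mutation reporter assays used to
    measure DNA polymerase fidelity. Aligns sequenced mutant reporter inserts
    to a reference target, left-normalizes indels, calls and groups mutation
    events, tabulates strand-collapsed error spectra, partitions errors by
    region, scans for positional hotspots, and computes fidelity statistics
    (background-corrected mutant frequency, gap-assay error rate, polymerase
    error frequency and its multiple-error correction, class-partitioned
    error frequencies with zero-count upper bounds). Includes a seeded
    simulator of an error-prone polymerase (templating-base-biased
    substitutions, homopolymer slippage indels, hairpin-associated complex
    events) and of the colony-screening readout, so every stage is
    exercisable end to end with parameter-recovery guarantees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
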