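Package: transcistor
Title: Direct Molecular Haplotyping with Solid-Phase Double-ARMS Bead Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for direct (non-statistical) haplotyping of
    highly polymorphic loci by multiplex double allele-specific PCR (double
    ARMS) captured on spectrally addressed bead arrays. Designs
    allele-specific primer panels over an allele alignment (3'-terminal
    discrimination, IUPAC wobbles, melting-temperature window,
    complementarity screens), mechanistically simulates the two-phase bead
    assay with an empirically parameterised noise model, decodes bead
    readouts into constituent haplotypes by cis-constraint assembly with
    built-in quality-control rules, matches assembled haplotypes to known
    alleles or flags them novel, and aggregates cohorts into allele-frequency
    tables and linkage-disequilibrium estimates, comparing composite
    (unphased) with direct (haplotype-based) coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
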