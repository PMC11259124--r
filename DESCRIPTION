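Package: ptvburden
Title: Gene-Burden Analysis of Premature-Terminating Variants in
    Case-Control Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@ptvburden.org",
           role = c("aut", "cre"))
Description: Rare-variant gene-burden analysis for loss-of-function
    (premature-terminating) variants in case-control resequencing studies.
    Provides a transcript-based consequence engine with HGVS coding and
    protein nomenclature (3'-normalisation, dup detection, frameshift
    Ter counting), genotype- and variant-level quality and rarity
    filters, a minimal PVS1-style pathogenic/likely-pathogenic rule,
    per-individual carrier collapsing, and 2x2 odds-ratio estimation
    with Woolf (log-normal) confidence intervals against one or several
    control panels, including pooled-panel and age-restricted
    re-analyses, forest tables and plots. A synthetic-cohort simulator
    generates transcripts, variant pools and multi-sample VCFs with
    known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
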