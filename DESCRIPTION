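Package: ligatyper
Title: Multiplex Ligation-Based SNP Genotyping: Panel Design, Simulation and Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for multiplex ligation detection reaction (MLDR) SNP
    genotyping read out by capillary electrophoresis. Designs collision-free
    dye-by-size probe panel layouts, constructs allele-specific ligation probe
    sets from flanking sequence with nearest-neighbor melting temperature
    control, simulates fragment-analysis peak tables for known genotypes,
    decodes peak tables back to genotypes via ladder-based size calling and
    allele-ratio zygosity rules, and interprets calls under gene-specific
    inheritance modes (autosomal recessive, dominant, X-linked, mitochondrial).
    Ships a built-in 32-variant hereditary hearing loss panel with cohort
    fixture generators for validation, control and patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
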