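Package: ribotraits
Title: Coupling Ribosomal Copy-Number Traits with Phenotypic Traits in
    Ciliated Protists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative framework linking per-cell 18S rDNA and rRNA copy
    numbers of ciliated protists to phenotypic traits (cell volume,
    macronuclear volume, maximum growth rate) across life-cycle stages.
    Provides cell-geometry and growth-rate computations, absolute qPCR
    quantification with amplification-efficiency estimation, log-log
    allometric power-law fitting with exact algebraic transformations among
    parameterizations, a resting-cyst fraction estimator based on the
    population rRNA/rDNA copy-number ratio and cell size, bivariate
    growth-rate prediction models, single-cell sequence-variant clustering
    with error-corrected divergence estimates, and seeded synthetic-data
    generators that emulate the statistical structure of single-cell trait
    and amplicon data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
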