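Package: thermoswap
Title: Analysis of Combinatorial Allele-Replacement Panels for Polygenic
    Temperature Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting a polygenic trait from a combinatorial
    allele-replacement (gene swap) strain panel in budding yeast. Converts
    replicate optical-density and colony-count measurements into growth
    efficiency, bounded logistic growth parameters, and CFU/mL/OD viability;
    estimates per-locus allele effects marginally and along a gene-stacking
    path through genotype space; builds a bootstrap additive-expectation null
    to quantify and classify epistasis (magnitude, masking, sign); and runs
    the rank-test and binomial trend inference with Benjamini-Hochberg
    correction. Ships a ground-truth-known synthetic panel generator that
    emulates the experimental design, so every stage is verifiable without
    raw data.
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
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
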