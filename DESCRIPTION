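Package: hegcor
Title: Haseman-Elston Genetic Correlations and Meta-Trait QTL Mega-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of narrow-sense heritability and cross-cohort
    genetic correlations of complex traits in multiparental outbred
    populations (e.g. Diversity Outbred mice) via Haseman-Elston
    regression, with an empirically calibrated standard-error correction
    factor. Includes kinship computation from biallelic dosages or
    founder-haplotype probabilities, interpolation of probabilities onto
    a common pseudomarker grid, a common phenotype adjustment and
    normalization workflow, genetic-correlation-guided hierarchical
    clustering of traits into meta-traits, additive founder-haplotype
    genome scans with permutation-based significance thresholds and
    false-discovery rates, and a synthetic-data generator for end-to-end
    validation of the whole pipeline.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
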