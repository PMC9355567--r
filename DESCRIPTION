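Package: barfit
Title: Barcode-Based Fitness Assays and the Decomposition of Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pooled barcode-sequencing fitness assays in microbial
    populations: turning raw amplicon reads into per-lineage count matrices
    (quality filtering, flank-anchored barcode extraction, and
    single-bp-deletion-neighborhood error correction), estimating per-mutation
    fitness effects with propagated standard errors (neutral-reference
    normalization, contamination and outlier filters, combined-barcode
    replicates, inverse-variance meta-estimates), summarizing the distribution
    of fitness effects (DFE) across evolved genetic backgrounds with three
    treatments of missing measurements, and decomposing epistasis into a
    fitness-correlated component and idiosyncratic population-specific steps
    via BIC forward selection among anchored linear models. A seeded synthetic
    study generator (serial-transfer dynamics, bottleneck and read sampling,
    injected outliers, contamination spikes, and biased missingness) provides
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
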