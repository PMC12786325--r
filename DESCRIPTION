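Package: aliflow
Title: Liquid-Level Control Simulation and LFP Analytics for Air-Liquid-Interface MEA Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational companion to an air-liquid-interface (ALI)
    microfluidic platform for organotypic brain cultures on multi-electrode
    arrays (MEA). Provides a discrete PID liquid-level controller with a
    simulated open-dish fluid plant; seeded generators for synthetic MEA
    recordings with condition-dependent spectral structure and for synthetic
    protein abundance tables; local field potential (LFP) analysis (amplitude
    threshold spike detection, fragment-wise power spectral densities, band
    summaries); random-forest condition classification with class-repartition,
    confidence-upon-prediction and chi-square reporting; and rank-based
    proteomics comparison with presence filtering, low-quantile imputation and
    trimmed-mean-of-M-values (TMM) scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
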