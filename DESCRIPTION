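Package: hostSDM
Title: Host-Constrained Maximum-Entropy Species Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A maximum-entropy (Gibbs) species distribution model with L1
    regularization, feature expansion (linear, quadratic, product, hinge,
    threshold), AICc-based tuning over feature-class and regularization
    multiplier grids, replicate evaluation with presence-background AUC,
    permutation importance and jackknife gains. Adds an obligate-parasite
    host constraint: host suitability enters the parasite model as a
    spatially explicit predictor and a conditional probability transfer
    zeroes parasite suitability wherever host suitability falls below a
    parasitism threshold. Includes four-level suitability classification,
    binary change maps, area-weighted centroid shifts, an area-difference
    rate statistic for scenario comparison, land-use overlay summaries,
    ESRI ASCII grid input and output with spherical cell areas, occurrence
    thinning, a collinearity-aware variable filter, and a synthetic
    landscape generator so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
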