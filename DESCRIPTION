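Package: swcrtbalance
Title: Sequence Balancing and Imbalance Indices for Stepped-Wedge Cluster
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sequential imbalance of site-level characteristics in
    stepped-wedge cluster randomized trials (SWCRTs) with rank-correlation
    based indices for linear, quadratic, and seasonal trends in crossover
    timing, and combines them into a weighted overall index. Provides
    exhaustive enumeration and random sampling of randomization sequences,
    percentile-targeted and minimal-imbalance sequence selection with random
    tie-breaking, a cross-sectional SWCRT outcome simulator under constant
    and gradually increasing ("learning") treatment effects with random-slope
    and cluster-by-time sensitivity variants, linear mixed-model estimation
    of the treatment effect via 'lme4', and a Monte-Carlo harness reporting
    relative root mean square error and relative mean bias over scenario
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
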