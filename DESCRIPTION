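Package: threatseg
Title: Resting-State Network Segregation and Top-Down Threat Bias in Pain
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the segregation of resting-state brain
    networks relates to top-down threat bias in pain perception.  The
    package builds functional connectivity matrices from region-of-interest
    (ROI) BOLD time series, applies Fisher z-transformation and proportional
    thresholding, computes the system-segregation statistic per network and
    whole-brain across a threshold grid, detects subject-specific modules by
    Louvain and Girvan-Newman modularity maximization, scores cued-threat
    pain bias from trial tables and assigns bias groups by K-means, and runs
    the inferential layer (normality-gated correlations, group t-tests,
    repeated-measures ANOVA, nuisance-covariate control).  A synthetic-data
    generator with planted brain-behavior effects makes the whole pipeline
    testable end-to-end without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
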