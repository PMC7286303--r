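Package: longconn
Title: Longitudinal Structural and Functional Brain Connectome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structural (fractional-anisotropy-weighted, fiber-density-weighted
    and binary) and functional (partial-correlation) brain connectomes from
    region-labeled tractography streamline tables and regional resting-state
    time series, computes global graph measures (degree, strength, clustering,
    global and local efficiency), localizes group differences in connectivity
    with the network-based statistic, compares groups per timepoint with
    Kruskal-Wallis tests under false-discovery-rate control, and models
    longitudinal group-by-age effects and connectivity-cognition relationships
    with linear mixed-effects models. A seeded synthetic-cohort generator
    emulates a two-group longitudinal rodent imaging study (atlas, dropout,
    planted subnetwork effects, working-memory outcomes) so the full pipeline
    is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
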