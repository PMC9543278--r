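Package: ecodivgrid
Title: Millennium-Scale Ecosystem Diversity Trends from Gridded Land-Use Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify long-term change in the diversity of ecosystem
    types from gridded fractional land-use reconstructions in the LUH2 "states"
    schema. Provides a SummarizedExperiment-based container for cells x types x
    years fraction grids; equal-area regridding with area-conserving
    reapportionment; biome/region overlay with boundary-cell removal; grain
    aggregation; three ecosystem classification schemes (9, 61 and 126 types);
    per-cell alpha-diversity metrics (richness, Pielou evenness, Shannon,
    Gini-Simpson, Rao quadratic entropy with a compositional dissimilarity
    matrix); pairwise beta-diversity (Jaccard and Bray-Curtis) with
    turnover/nestedness and balanced/gradient decompositions; centurial and
    decadal window averaging with baselines and net change; land-area-weighted
    spatial means; stratified bootstrap interdecile bands; and a mean pairwise
    dissimilarity estimator across grain and extent with subsampled draws. A
    seeded synthetic-scenario generator emulates the LUH2 schema so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    ncdf4,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
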