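Package: pondscape
Title: Longitudinal Habitat-Loss Biodiversity Analysis for Pond Metacommunities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying biodiversity change in a two-epoch pond
    metacommunity under habitat loss. Implements sample-based rarefaction with
    resampled species-accumulation curves and quantile-regression confidence
    envelopes (by habitat number and by cumulative habitat area), expected
    species loss under the sampling-only null, penalized-spline competition of
    habitat number versus habitat area as richness predictors, habitat-network
    closeness centrality and its temporal change, permutation effect sizes for
    alpha and beta diversity, binomial and Gaussian driver models with
    commonality (pure/shared variance) partitioning, and a synthetic landscape
    generator that emulates the statistical structure of a saline-pond
    metacommunity so the whole pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    vegan,
    igraph
Config/testthat/edition: 3
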