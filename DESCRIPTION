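Package: farmscape
Title: Landscape Composition and Heterogeneity Effects on Farmland Bird
    Species Richness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models spatial and temporal variation in farmland bird species
    richness as a function of landscape composition and of the compositional
    and configurational heterogeneity of the natural and production
    components of agricultural landscapes. Computes FRAGSTATS-style
    landscape metrics on categorical raster buffers, builds transformed
    predictor matrices, performs two-stage information-theoretic multimodel
    inference (AICc, Akaike weights, summed variable-set weights, averaging
    of partial standardized regression coefficients with per-model relative
    importance), and checks spatial autocorrelation with bootstrap spline
    correlograms. A synthetic-landscape generator with known ground truth
    makes every stage of the pipeline verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
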