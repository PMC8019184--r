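Package: mantelmc
Title: Sampling-Design Bias in Mantel-Based Migratory Connectivity Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for quantifying how spatial sampling design
    biases Mantel-correlation estimates of migratory connectivity. Provides
    generators for abstract migratory populations (uniform and patchy) with
    tunable connectivity, spatially clustered populations over arbitrary range
    polygons via Gaussian random fields and longitudinal-rank matching, the
    marking-design scenarios (single areas, 3x3 spread grids, per-patch areas,
    top-density discrete sites), a from-scratch Mantel statistic with
    permutation testing and blockwise whole-population computation, and
    replicate experiment runners with bias-versus-zone and bias-versus-global
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
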