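Package: corridors
Title: Multi-Species Wildlife Corridor Modelling on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to delineate wildlife corridors for multiple species from
    presence records and raster environmental predictors. Fits per-species
    ensemble habitat-suitability models (with pseudo-absence generation,
    geographic thinning and AUC-thresholded learner retention), stacks them
    into a multi-species suitability index, converts suitability to linearly
    and non-linearly scaled landscape-resistance surfaces, and computes both
    least-cost (cost-weighted distance, normalized corridor, quantile slice)
    and circuit-theory (voltage, current, effective resistance) connectivity
    between two terminal reserves. Includes a seeded synthetic-landscape
    generator emulating transect-sampled savanna presence data, a comparison
    layer (pairwise map correlations, corridor overlap, proxy-species
    ranking), and a reproducible pipeline driver with ESRI ASCII grid and CSV
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    glmnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
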