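Package: imma
Title: Muscle Moment-Arm Geometry and Phylogenetic Adaptive-Optimum Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes instantaneous muscle moment arms (IMMA) of a hip
    extensor from 3D bone landmarks across a standardized grid of hip
    extension and abduction poses, together with the osteological in-lever,
    and compares macroevolutionary models of moment-arm evolution across
    locomotor lifestyles: Brownian motion versus multi-optimum
    Ornstein-Uhlenbeck models with a body-size direct-effect covariate,
    fitted by grid-search profile likelihood over phylogenetic half-life
    and stationary variance. Includes maximum-likelihood Mk fitting and
    stochastic character mapping of discrete lifestyle regimes, consensus
    regime painting, AICc/SIC model ranking, and a fully seeded synthetic
    generator of hip geometries, ultrametric trees, lifestyle histories,
    and traits for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
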