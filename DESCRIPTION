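Package: crabipm
Title: Integrated Integral Projection Models for Size-Structured Removal Programs
Version: 0.1.0
Authors@R:
    person("Drayton", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits and forecasts a Bayesian state-space integral projection
    model (IPM) for size-structured populations under removal (harvest)
    pressure, motivated by invasive European green crab (Carcinus maenas)
    control programs. The latent process couples seasonal von Bertalanffy
    growth, size-dependent natural mortality, density- and size-dependent
    overwinter mortality, and annual recruitment pulses on a discretised
    size grid. Three data streams are integrated in a joint likelihood:
    multi-year size-binned removal counts with size-selective trap hazards
    and Dirichlet-multinomial trap composition, size-at-age records, and
    mark-recapture occasions. Includes a synthetic-data generator, an
    adaptive Markov chain Monte Carlo sampler, WAIC model selection over
    overwinter-mortality formulations, posterior predictive checks, and
    stochastic equilibrium forecasts under trapping-effort scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
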