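Package: avramicarc
Title: Avrami Nucleation-and-Growth Modelling of Single-Cell Cancer
    Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric multi-hit modelling of single-cell neoplastic
    transformation using the kinetics of nucleation and growth
    (Johnson-Mehl-Avrami-Kolmogorov theory). Provides closed-form
    probabilities that randomly placed DNA mutations hit a threshold
    volume of proto-oncogenes, a Monte Carlo simulator of oncogene
    cluster nucleation and growth in the DNA volume that reproduces the
    Avrami critical index k = xi + 2, and a fitting engine for sigmoidal
    cumulative cancer-incidence curves against mutation count or age
    (converted at a mutations-per-year rate), with fixed-k profiling and
    bootstrap confidence intervals. Includes a seeded synthetic-cohort
    generator emulating registry-style cumulative incidence tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
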