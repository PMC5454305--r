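Package: lossyRD
Title: Rate-Distortion Analysis of Lossy Perceptual Coding in Random
    Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the cost of perception in large unstructured
    environments with rate-distortion theory. Draws random distortion
    matrices (shifted exponential, lognormal, and pairwise-correlated
    ensembles), computes optimal lossy codebooks and rate-distortion
    curves by Blahut-Arimoto fixed-point iteration with a beta sweep
    tiling the distortion axis, evaluates closed-form upper and lower
    bounds on R(D), and runs ensemble experiments with bootstrap
    confidence intervals that separate the high-fidelity regime (rate
    grows as log N) from the low-fidelity regime (rate asymptotes) at
    the minimal confound.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'environments.R'
    'rd_solver.R'
    'bounds.R'
    'scaling.R'
    'config.R'
    'io.R'
    'show-methods.R'
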