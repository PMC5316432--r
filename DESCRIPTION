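Package: anfiscall
Title: Neuro-Fuzzy Confidence Estimation for DNA Base Calling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-base confidence estimation for DNA base calling with a
    hierarchical adaptive neuro-fuzzy inference system (ANFIS). Three
    two-input zero-order Sugeno subsystems score the peakness, height and
    spacing of chromatogram trace peaks; a three-input main system combines
    the three feature scores into a confidence value in [0,1]. Includes
    grid-partition rule generation, backpropagation and hybrid
    least-squares/gradient training, a synthetic trace-feature generator
    for desk-scale experiments, JSON model serialization and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
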