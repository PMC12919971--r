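Package: reachbias
Title: Generative Models of Systematic Motor Biases in Goal-Directed Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling the systematic angular and radial biases seen
    in center-out reaching movements. Implements a family of generative bias
    models (diagonal-attraction target bias, vector- and joint-based
    proprioceptive biases, visuo-proprioceptive transformation bias, visual
    depth bias, and their hybrids), scenario-dependent predictions
    (visible, hidden or perturbed start position), maximum-likelihood fitting
    with BIC-based model comparison, vertical/horizontal shift analysis of the
    bias function after implicit visuomotor adaptation, split-half
    reliability with noise-ceiling normalization, and a seeded synthetic
    cohort generator that emulates the trial structure of typical center-out
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
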