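Package: choicelca
Title: Leaky Competing Accumulator Modelling of Inclusive and Exclusive Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates multi-alternative value-based decisions with a modified
    Leaky Competing Accumulator (mutual inhibition, input gain, leak, Gaussian
    noise and a collapsing decision boundary), generates complete synthetic
    rating/choice/conflict studies under constrained choice-set designs, fits
    the associated mixed-effects regression battery (reaction time, accuracy,
    choice conflict and voluntary subsequent selections), and identifies which
    model parameter a task manipulation altered by simulate-regress-compare
    grid search. Built to study how framing a choice as inclusive (picking
    more options remains possible) rather than exclusive changes the speed,
    accuracy and experienced conflict of the first decision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
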