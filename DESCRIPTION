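Package: groupsim
Title: Multiagent Reinforcement Learning Testbed for Emergent In-Group Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale multiagent reinforcement-learning testbed for studying
    how in-group favoritism emerges from differential exposure alone. Provides a
    sprite-based foraging gridworld in which agents collect colored resources and
    gain reward by interacting with ready partners, a two-population
    in-group/mixed server scheduler, independent actor-critic learners
    (convolutional + recurrent pixel policies and compact symbolic policies),
    frozen-policy dual-choice behavioral probes, and the derived group-bias,
    chance-normalization and individuation statistics, together with scripted
    fixture policies so every environment and metric operation is testable
    without training.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
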