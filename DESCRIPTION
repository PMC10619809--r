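Package: animatphi
Title: Integrated Information and Surprisal in Evolved Animats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying the relationship
    between integrated information (IIT 3.0 Phi) and sensory surprisal in
    evolved artificial agents ("animats"). Provides a deterministic
    block-catching task world, Markov-brain agents built from per-node logic
    gates, a genetic algorithm with line-of-descent tracking, a complete
    IIT 3.0 engine for small binary networks (cause/effect repertoires,
    mechanism-level phi, concepts, system-level Phi and main-complex search,
    with exact earth mover's distances solved as transportation problems),
    empirical goal priors built from perfect-fitness agents with add-one
    smoothing, per-timestep surprisal scoring, and the downstream
    evolutionary-time and within-trial covariation analyses
    (cross-correlations, correlation profiles, fluctuation regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    boot,
    withr
Config/testthat/edition: 3
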