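Package: groomnet
Title: Dynamic Social Network Analysis of Allogrooming in Dairy Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the week-to-week dynamics of directed
    allogrooming (social licking) networks in dairy cattle. Builds weekly
    weighted and binary contact networks from timestamped behavioural event
    logs (with the 20-second bout-merging rule), computes descriptive network
    statistics and tie-change/Jaccard stability summaries, derives Lamprecht
    dominance indices and rank classes from headbutt records with
    intraclass-correlation reliability statistics, and fits stochastic
    actor-oriented models (SAOMs) to network panels with a built-in
    continuous-time micro-step simulator, Robbins-Monro Method-of-Moments
    estimation, convergence diagnostics, auxiliary-statistic goodness of fit,
    time-heterogeneity testing and forward model selection. A synthetic-herd
    generator produces event logs and network panels from known ground truth
    so every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
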