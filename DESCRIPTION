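Package: burstfit
Title: Multiscale Survival Modelling of Human Interevent Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the waiting times between an individual's consecutive
    events with a multiscale survival process: a four-parameter hazard
    whose induced distribution spans a quick-response plateau, a power-law
    burst regime and an exponential tail. Provides exact distribution
    functions, per-individual maximum-likelihood fitting, baseline
    waiting-time families (exponential, Pareto with tuned lower cutoff,
    Weibull, log-normal), Kolmogorov-Smirnov, chi-square and
    Cramer-von Mises goodness-of-fit protocols with population summaries,
    data-cropping analysis, an exact renewal simulator with population
    heterogeneity, and event-log utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
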