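Package: coalrank
Title: Coalition Dynamics, Elo-Rating Trajectories and Rank-Mediated
    Reproductive Success in Male Macaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the consequences of male-male coalitions for
    dominance-rank trajectories and reproductive success in primate groups.
    Computes sequential Elo-rating dominance trajectories from decided dyadic
    agonistic interactions, classifies coalition events into all-down,
    bridging and all-up configurations, scores coalition feasibility from
    standardized ratings, assembles event-by-male-by-future-offset model
    tables, fits linear mixed models of future rank and a binomial mixed
    model of siring probability with likelihood-ratio tests and parametric
    bootstrap prediction bands, and includes an agent-based synthetic-data
    generator with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
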