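Package: growfix
Title: Evolutionary Game Dynamics on Growing Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of cooperation in growing
    networked populations represented as sequential temporal networks
    (monotone sequences of snapshots of a final static network). Implements
    exact neutral-drift fixation probabilities with closed-form growth rules,
    exact weak-selection first-order coefficients and critical
    benefit-to-cost ratios via coalescence-time linear systems, a fast
    mean-field approximation built from degree moments, a compiled
    Monte-Carlo simulator of donation-game death-birth dynamics under two
    growth/evolution timescale regimes, and generators for lattice,
    random-regular, and preferential-attachment growth schedules as well as
    a reader for contact-triplet ("t i j") data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
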