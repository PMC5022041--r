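Package: cascadenet
Title: Detecting and Controlling Event-Cascade Emergence in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the stationary-nonstationary (SN) transition of
    event-occurrence processes well below the classic epidemic threshold.
    Provides microscopic simulators for a susceptible-infected-susceptible
    (SIS) Markov process with spontaneous activation and for univariate and
    multivariate Hawkes self-exciting point processes (including a
    refractory-period revision); a stationarity detector based on
    mean-squared-error optimal histogram bin-size selection; the analytic
    cascading statistic C built from the Leontief inverse of the interaction
    matrix, with its critical value of 2 and critical reproduction ratio
    solver; network generators (uniform, Erdos-Renyi, Barabasi-Albert,
    Watts-Strogatz, ring lattice, block "extreme" configurations, Zachary's
    Karate Club); and a greedy connection-reallocation optimizer that drives
    a network across the SN transition while conserving its connection
    density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
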