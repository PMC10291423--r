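Package: reproskew
Title: Principal-Agent Models of Reproductive Skew in Cooperative Breeders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Solves and simulates a two-male principal-agent game of
    reproductive skew between a dominant (Alpha) and a subordinate helper
    (Beta) in a cooperatively breeding bird. The dominant controls the
    paternity share of the subordinate's brood (the "wage"); the subordinate
    best-responds with feeding effort that carries a quadratic mortality
    cost. The package provides closed-form equilibria, participation- and
    incentive-constraint regime classification, Gini-based skew metrics,
    brute-force Nash/ESS/Pareto verification oracles, deterministic adaptive
    dynamics, a Wright-Fisher mutation-selection simulator, parameter sweeps
    for comparative statics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
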