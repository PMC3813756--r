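Package: forestgov
Title: Forest-Cover Dynamics Under Incentive-Based Governance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled human-environment Markov chain model of forest-cover
    dynamics in a landscape of land parcels whose owners decide each year
    whether to deforest, based on socially learned expected utilities and a
    logit choice rule. Implements three governance strategies (a yearly
    conservation incentive, a one-time deforestation penalty, and a one-time
    reforestation incentive) in both a stochastic agent-based engine and a
    deterministic mean-field (density) engine, together with closed-form and
    numerical equilibria, local stability analysis via the Jacobian spectral
    radius, regime classification into four qualitative landscape outcomes,
    parameter sweeps, scenario presets, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
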