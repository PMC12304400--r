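Package: banditmetrics
Title: Measurement Properties of Exploration Strategies in Few-Armed Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well few-armed bandit tasks measure
    exploration strategies. Generates the reward structures of three bandit
    paradigms (a Horizon task, a drifting two-armed bandit, and a four-armed
    restless bandit), implements Kalman-filter learning with upper-confidence
    bound and logistic choice rules (original and improved model variants),
    simulates synthetic two-session cohorts with a latent two-factor structure
    over subject-level parameters, and fits the models by maximum likelihood
    and by hierarchical empirical-Bayes shrinkage. Downstream analyses cover
    parameter recovery, test-retest reliability via intraclass correlations,
    convergent validity matrices, reward-optimality grids, the information
    value of forced exploration, and confirmatory factor models with
    correlated residuals, fit indices (CFI, RMSEA) and BIC-approximate Bayes
    factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
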