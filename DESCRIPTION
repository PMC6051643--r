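Package: motorgamble
Title: Prospect-Theory and Approach-Avoidance Models of Motor Gambling Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing go/no-go motor gambling choices: a 24-member
    family of prospect-theory and Pavlovian approach-avoidance softmax choice
    models, per-participant bounded maximum-likelihood fitting with random
    restarts, AIC/BIC model comparison with subject-level tallies and
    likelihood-ratio tests, parameter- and model-recovery diagnostics,
    model-free behavioural statistics (optimality discrepancy, binned
    gamble-rate curves with exponential fits, partial Spearman correlations
    with BCa bootstrap intervals and permutation p-values), and a synthetic
    cohort generator emulating an app-based motor gambling study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
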