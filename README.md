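# motorgamble

Computational modelling of **go/no-go motor gambling decisions**: do people
decide to attempt a risky motor action based purely on subjective utilities
(prospect theory), or does a value-independent Pavlovian bias — approach
toward reward, avoidance of punishment — shift the decision as well, and how
do these components change across the adult lifespan?

The package is written for behavioural and cognitive scientists analysing
trial-by-trial choice data from motor gambling tasks: each trial offers a
certain outcome (+10 or −10 points) against a gamble whose payoff (±20/60/100
or 0) depends on successfully executing a speeded tapping movement, with
success probability varying by target size, device screen size and age group.

## The models

Subjective value follows a two-part power function with risk preference
α ∈ [0, 1] and loss aversion λ fixed at 1:

    v(O) = O^α        (O ≥ 0)
    v(O) = −λ(−O)^α   (O < 0)

A gamble [p → O₁; (1−p) → O₂] has utility U = w(p)·v(O₁) + (1−w(p))·v(O₂),
where w(p) is either the objective probability or the one-parameter weighting
w(p) = exp(−(−ln p)^γ). Choice is softmax in the utility difference with
inverse temperature μ ∈ (0, 10]:

    F = 1 / (1 + exp(−μ(U_gamble − U_certain)))

Approach-avoidance (AA) models add a Pavlovian offset δ ∈ [−1, 1] after the
softmax and clamp: F ← max(0, min(F + δ, 1)). Crossing joint/split α,
joint/split μ, δ absent/joint/split, and linear/weighted probability yields
the 24-model family (`enumerate_models()`); the AA variant
[α, μ, δ⁺, δ⁻] has spec code `"a0m0d2w0"`.

The package provides per-participant bounded multi-start maximum likelihood
(`fit_mle`, `fit_cohort`), an exhaustive `grid_oracle` for verification,
AIC/BIC comparison with subject-level winner tallies (`compare_models`),
individual likelihood-ratio tests (`lr_test`, `lr_split_tally`),
parameter/model recovery and model-falsification curves
(`parameter_recovery`, `model_recovery`, `predicted_curves`), model-free
behavioural statistics (`optimality_discrepancy`, `binned_gamble_rate`,
`fit_exponential`, `partial_spearman` with BCa bootstrap CIs and permutation
p-values, `estimation_error`), and a synthetic cohort generator
(`cohort_config`, `generate_cohort`, `generate_estimation_study`) emulating
the task's data structure. `run_pipeline()` orchestrates
generate → fit → select → recover → stats over flat CSV/JSON artefacts
(a thin CLI lives at `inst/scripts/motorgamble-cli.R`).

## Worked example

```r
library(motorgamble)

cfg    <- cohort_config(n_per_age_group = rep(10L, 6L), seed = 7L)
cohort <- generate_cohort(cfg)
#> synthetic_cohort: 60 participants, 2520 trials (seed 7)

st   <- estimate_success_table(cohort$trials, mode = "group")
fits <- fit_cohort(cohort$trials, st,
                   specs = lapply(c("a0m0d2w0", "a0m0d0w0"), parse_spec_code),
                   n_restarts = 10L, seed = 7L)
compare_models(fits)
#> Summed-BIC winner: a0m0d0w0 | summed-AIC winner: a0m0d2w0
#>      code      aic      bic
#>  a0m0d0w0 2043.005 2251.526
#>  a0m0d2w0 1893.587 2310.628
```

The AA model gains about 150 summed log-likelihood points over prospect
theory (AIC winner), but at this small scale BIC's stiffer complexity
penalty (2 ln 42 per participant for the two extra δ parameters) still
prefers the 2-parameter PT model: the default generator's approach bias
declines with age, so half the cohort has offsets near zero. Group-level
inference on the fitted Pavlovian approach parameter recovers the generating
age gradient regardless:

```r
aa   <- merge(fits[fits$code == "a0m0d2w0", ],
              unique(cohort$trials[, c("participant_id", "age_group",
                                       "gender", "education")]),
              by = "participant_id")
partial_spearman(aa$delta_plus, aa$age_group,
                 data.frame(gender    = as.integer(factor(aa$gender)),
                            education = as.integer(factor(aa$education))),
                 n_boot = 1000L, n_perm = 1000L, seed = 7L)
#> partial Spearman r = -0.402, 95% CI [-0.632, -0.135], p = 0.001998 (n = 60)
```

The reward approach bias δ⁺ declines with age group (negative partial
Spearman correlation, controlling for gender and education), the package's
analogue of the headline lifespan effect.

## Package layout

- `R/task_model.R` — schedule, expected values, screen binning, success tables
- `R/choice_models.R` — value function, weighting, softmax + offset, 24-model family
- `R/inference.R` — log-likelihood, multi-start MLE, grid oracle, cohort fitting
- `R/model_selection.R` — AIC/BIC, pseudo-R², comparison report, LR tests
- `R/recovery.R` — parameter/model recovery, predicted curves
- `R/behaviour_stats.R` — optimality, binned curves, partial Spearman, estimation error
- `R/synthetic_data.R` — cohort configuration and generators
- `R/pipeline.R` — `run_pipeline`, `validate_trials`, config I/O
- `vignettes/motor-gambling-models.Rmd` — the methods vignette
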