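---
title: "Modelling approach-avoidance biases in motor gambling decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling approach-avoidance biases in motor gambling decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorgamble)
```

## The scientific problem

In a go/no-go motor gamble, a player decides on each trial between a certain
outcome (a small reward of +10 points, or a small punishment of −10) and a
gamble whose payoff depends on successfully executing a speeded tapping
action: a larger reward (20/60/100) on success and 0 on failure, or — in the
punishment domain — 0 on success and a larger loss (−20/−60/−100) on failure.
The probability of motor success varies with target size, device screen size
and the player's age, so rational choice requires integrating one's own motor
competence into the valuation of the gamble.

Two families of computational models compete to explain such choices:

* **Prospect theory (PT)**: choices are driven entirely by subjective
  utilities. Value is transformed by a two-part power function and compared
  through a softmax.
* **Approach-avoidance (AA)**: in addition to the utility comparison, a
  *Pavlovian* bias shifts the probability of acting — approach toward reward
  cues, avoidance of punishment cues — independently of the option values.

This package implements both families, fits them to trial-by-trial choice
data by maximum likelihood, compares them with information criteria and
likelihood-ratio tests, and provides recovery diagnostics and model-free
behavioural statistics. Because the real cohort data are not bundled, a
first-class synthetic-data module generates cohorts with the same schema and
statistical structure, so the full pipeline runs end-to-end out of the box.

## The model family

**Value function.** For an outcome $O$ in points,

$$v(O) = \begin{cases} O^{\alpha} & O \ge 0 \\ -\lambda\,(-O)^{\alpha} & O < 0 \end{cases}$$

with risk preference $\alpha \in [0, 1]$ and loss aversion $\lambda$ fixed at
1 (no gamble in this task mixes gains and losses, so $\lambda$ is not
identifiable). $\alpha < 1$ produces risk aversion for gains and risk seeking
for losses: at $\alpha = 0.8$ the reward gamble [50% of 20; 50% of 0] is
worth $0.5 \times 20^{0.8} = 5.49$ while the certain 10 is worth
$10^{0.8} = 6.31$.

**Probability weighting.** Optionally, objective probabilities are distorted
by the one-parameter form $w(p) = \exp(-(-\ln p)^{\gamma})$, with
$\gamma = 1$ the identity. The utility of a gamble
$[p \to O_1;\ (1-p) \to O_2]$ is $U = w(p)\,v(O_1) + (1 - w(p))\,v(O_2)$;
because one gamble outcome is always 0 and $v(0) = 0$, the linear case
reduces to $p \, v(O)$.

**Choice rule.** The probability of gambling is the softmax
$F = \left(1 + e^{-\mu (U_{gamble} - U_{certain})}\right)^{-1}$ with inverse
temperature $\mu$. AA models then add the Pavlovian offset and clamp:
$F \leftarrow \max(0, \min(F + \delta, 1))$. The offset is added *after* the
softmax and the offset itself is never clamped. Positive $\delta$ increases
gambling regardless of value; negative $\delta$ suppresses it.

**The 24 variants.** Each of $\alpha$ and $\mu$ may be joint or split by
domain (reward `_plus` / punishment `_minus`); $\delta$ may be absent, joint,
or split; weighting linear or with a free $\gamma$:
$2 \times 2 \times 3 \times 2 = 24$. `enumerate_models()` orders them
PT-linear, PT-weighted, AA-linear, AA-weighted, placing the PT variant
$[\alpha^+, \alpha^-, \mu^+, \mu^-]$ at position 4 and the AA variant
$[\alpha, \mu, \delta^+, \delta^-]$ (spec code `"a0m0d2w0"`) at position 10.
The remaining ordering within blocks is a package convention, stable across
releases. Models are addressed by a compact code `a{0,1}m{0,1}d{0,1,2}w{0,1}`
throughout result tables.

## Parameter estimation

Per participant, the log-likelihood of a parameter vector is the Bernoulli
sum $\sum_i y_i \ln F_i + (1 - y_i)\ln(1 - F_i)$ over trials, where $y_i$ is
the observed gamble/skip choice. Because the clamp permits $F$ of exactly 0
or 1, $F$ is clamped into $[\varepsilon, 1-\varepsilon]$ *inside the
logarithms only*, with $\varepsilon = 10^{-9}$.

`fit_mle()` maximises this likelihood with bounded quasi-Newton (L-BFGS-B)
local searches inside the box $\alpha \in [0,1]$, $\mu \in (0, 10]$ (lower
bound implemented as $10^{-6}$), $\delta \in [-1, 1]$, and, when present,
$\gamma \in (0, 5]$ starting at 1. Starting points are uniform random draws
within the box — 200 in the reference analysis; a handful suffices for the
42-trial design and is the default in the pipeline. Two fixed, well-scaled
starts (moderate and low temperature, zero offset) are always searched as
well, because the clamped likelihood is exactly flat wherever the softmax
saturates — a region that can swallow every random start when $\mu$ is drawn
uniformly from (0, 10]. Each participant's restart stream is derived from
(master seed, participant id), so cohort fits are reproducible regardless of
fitting order or parallel scheduling.

The optimiser's contract is checked against `grid_oracle()`, an exhaustive
evaluation of the likelihood on a regular grid over the parameter box (the
likelihood is vectorised over the grid, so ~5 × 10⁵ points evaluate in about
a second; the oracle refuses more than 10⁷ points).

Trials whose success probability cannot be resolved from the success table
are excluded from the likelihood and counted (`n_dropped`); $N$ in BIC and
pseudo-$R^2$ counts only used trials. Missing success-table cells propagate
as `NA`, never as 0 — a silent zero would bias the fitted utilities.

## Success probabilities

The success probability a participant faces is not a free parameter: it is
estimated from observed gambled trials as the average motor success across
all participants with the same age group, the same screen-size bin (nearest
of 4/6/8/10 inches, exact midpoints to the smaller bin) and the same target
level (`estimate_success_table(mode = "group")`). The individual mode keys
rates by (participant, target level) instead, as a robustness alternative.

## Model selection

`aic()` and `bic()` implement $-2\log L + 2k$ and $-2\log L + k \ln N$;
`pseudo_r2()` compares against the null model with
$\alpha = \mu = \delta = 0$, which predicts $F = 0.5$ on every trial, so the
null log-likelihood is $N \ln 0.5$ in closed form. `compare_models()` sums
criteria over participants, reports the smallest-summed-BIC model, tallies
per-alternative subject-level winner percentages (per-subject ties count
half to each side; summed-criterion ties break toward the smaller $k$, then
lexicographic code), and runs two-sided paired t-tests with Bonferroni
correction over the alternatives. `lr_test()` compares nested joint/split
pairs per individual ($\chi^2$, df = 1 per split); `lr_split_tally()` runs
the delta, alpha and mu splits used to ask which domain separation the data
actually demand.

## Recovery diagnostics

* `parameter_recovery()`: simulate choices from known "typical participant"
  parameters on a session template, refit, and summarise the recovered cloud
  (median, central 80% interval, truth coverage). The three default sets in
  `typical_parameter_sets()` span $\alpha$ 0.7–0.9, $\mu$ 0.15–0.5,
  $\delta^+$ 0.1–0.35, $\delta^-$ −0.3–−0.05 — the plausible region for this
  task. On 42-trial sessions the clouds are wide but centred; at ~1000
  trials $\alpha$ and the $\delta$s recover to within ±0.1 while $\mu$, which
  trades off against $\alpha$, is reliable to a factor of about two.
* `model_recovery()`: cohorts simulated under the AA winner are refit with
  both winners; BIC must select the generator, and must *reject* the AA
  model's extra parameters on PT-generated cohorts.
* `predicted_curves()`: the falsification check. Fitted models predict the
  gamble probability for every trial; averaged within (age group, domain,
  EV-difference bin), only split-$\delta$ models can produce a
  reward-above-punishment gap near $EV_{gamble} - EV_{certain} = 0$. A PT
  model with $\alpha < 1$ predicts the *opposite* ordering there (risk
  aversion for gains, risk seeking for losses), which is what makes the gap
  diagnostic rather than cosmetic.

## Model-free behavioural statistics

* `optimality_discrepancy()`: the optimal choice is to gamble iff
  $EV_{gamble} - EV_{certain} > 0$; the score is the mean absolute
  difference between observed and optimal choices per domain. Trials with an
  EV difference of exactly 0 are excluded — either action is optimal, and any
  coding would be arbitrary.
* `binned_gamble_rate()`: observed gamble proportions in half-open
  EV-difference bins anchored at 0 (width 10 points by default), with
  percentile bootstrap intervals; `fit_exponential()` summarises a curve by
  $y = a e^{-bx} + c$ (nonlinear least squares, $b \ge 0$, initialised from
  the curve's endpoints).
* `partial_spearman()`: the age analyses control for gender and education.
  All variables are rank-transformed; the ranks of the outcome and of age are
  residualised on the covariate ranks by least squares and the residuals
  correlated. Confidence intervals are BCa bootstrap over participants
  (10,000 resamples by default); p-values come from permuting age labels
  (10,000 by default) with the add-one correction
  $p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (1 + n_{perm})$, two-sided.
  Education enters as ordinal codes. Both the sidedness and the ordinal
  coding are package decisions where conventions differ.
* `estimation_error()`: for the probability-estimation control study, the
  per-trial error is the verbal estimate minus 100 if the action succeeded
  and minus 0 if it failed; calibrated estimators average to 0.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions; `generate_cohort()` simulates
them. What it emulates:

* the 42-trial schedule — 6 value combinations × 7 target levels, blocks 1–3
  presenting the three largest targets (one level per block, permuted),
  blocks 4–6 the next three, block 7 the smallest; combinations shuffled
  within block. The within-block order of the 6 combinations is a uniform
  random permutation (the original app's order is not documented);
* a success surface over 6 age groups × 4 screen bins × 7 target levels:
  logistic in level (declining), screen bin (improving), age (declining),
  with a mild age-by-level interaction, clipped to [0.02, 0.98]. Defaults
  (base rate 0.93 at the easiest cell, −0.55 logit per level, ±0.25 per
  screen/age step) put the easiest cells above 90% success and the hardest
  near 20–35%, the qualitative shape of the motor data this task produces;
* age-graded AA parameters: group medians interpolate linearly from young to
  old anchors — $\delta^+$ 0.35 → 0.05 (the steep decline of the approach
  bias is the headline effect), $\delta^-$ −0.10 → −0.25, $\alpha$
  0.85 → 0.70, $\mu$ flat at 0.5 — with truncated-normal heterogeneity
  (sd 0.08 for $\alpha$ and $\delta$, 0.15 for $\mu$) truncated at the model
  bounds;
* choices drawn Bernoulli from the generating AA model; motor outcomes drawn
  only on gambled trials (a skipped trial's outcome is unobservable, and is
  therefore never generated).

What it does **not** emulate: tap kinematics and movement times, the real
demographic composition, device-model idiosyncrasies, and any within-session
learning or fatigue — participants are stationary. Passing tests therefore
demonstrate that the estimation and inference machinery is correct and well
calibrated *under the model's assumptions*, not that the model is true of
human data.

The default cohort of 100 participants per age group (600 total) is the
scale at which the age gradient in $\delta^+$ is comfortably detectable by
the partial-correlation machinery; effects of this kind in small-effect
behavioural data genuinely need hundreds of participants.

## Numerical choices

* $\varepsilon = 10^{-9}$ for log clamping, applied only inside logarithms.
* $\mu$ lower bound $10^{-6}$ (the theoretical interval is open at 0).
* Degenerate inputs: all-missing success probabilities raise an error rather
  than returning a vacuous fit; constant variables in the partial
  correlation raise an error (residual sd below $n \times 10^{-10}$ counts
  as constant); a constant curve makes the exponential fit's $R^2$ `NA`.
* Summed-criterion ties in model comparison are detected with a relative
  tolerance of $10^{-8}$ so floating-point accumulation order cannot split
  a genuine tie.
* Test and example problem sizes are scaled-down versions of the reference
  analysis (e.g. 6–10 restarts instead of 200, cohorts of tens to hundreds
  instead of tens of thousands, 100–500 bootstrap/permutation replicates
  instead of 10,000); the package defaults keep the reference values where
  the quantity is a scientific claim (restart count default, replicate
  defaults) and the scaled values where it is plumbing.

## Known limitations

* $\lambda$ is fixed at 1 by design; do not reuse these fits for tasks with
  mixed-sign gambles.
* $\mu$ and $\alpha$ trade off; at 42 trials per participant, individual
  $\mu$ estimates are order-of-magnitude statements, and group-level
  contrasts should be preferred.
* The group success table assumes participants know their own success
  probability and that it is exchangeable within (age, screen, level) cells;
  the individual mode relaxes exchangeability but needs enough gambled
  trials per level.
* BCa intervals with few bootstrap replicates can hit extreme order
  statistics; the implementation returns `NA` bounds in that case rather
  than fabricating an interval.
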