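test_that("log-likelihood matches the Bernoulli sum with clamped logs", {
  off <- make_template_offers(1L)
  null_spec <- parse_spec_code("a0m0d1w0")
  # coin-flip model on 42 trials
  off$y <- rep(c(0L, 1L), 21L)
  ll <- log_likelihood(c(alpha = 0, mu = 0, delta = 0), null_spec, off,
                       check = FALSE)
  expect_equal(ll, 42 * log(0.5), tolerance = 1e-12)
  # single trial, y = 1, F = 0.8 via a pure offset
  one <- data.frame(p = 0.5, O1 = 20, O2 = 0, Oc = 10, domain = "reward",
                    y = 1L)
  ll1 <- log_likelihood(c(alpha = 1, mu = 1e-6, delta = 0.3), null_spec, one)
  expect_equal(ll1, log(0.8), tolerance = 1e-4)
  # a perfect fit is bounded by the epsilon clamp, never above 0
  off$y <- 1L
  llp <- log_likelihood(c(alpha = 1, mu = 10, delta = 1), null_spec, off)
  expect_lte(llp, 0)
  expect_gt(llp, 42 * log(1 - 1e-9) - 1e-6)
})

test_that("MLE recovers generating parameters from a long session", {
  off <- make_template_offers(24L, seed = 5L)  # 1008 trials
  truth <- c(alpha = 0.8, mu = 0.3, delta_plus = 0.2, delta_minus = -0.2)
  off$y <- simulate_choices(off, truth, aa_spec, seed = 11L)
  fit <- fit_mle(off, aa_spec, NULL, n_restarts = 8L, seed = 2L)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta_hat[c("alpha", "delta_plus", "delta_minus")] -
                      truth[c("alpha", "delta_plus", "delta_minus")])), 0.1)
  # temperature trades off against alpha; the contract is a factor of two
  expect_gt(fit$theta_hat[["mu"]], truth[["mu"]] / 2)
  expect_lt(fit$theta_hat[["mu"]], truth[["mu"]] * 2)
  # reported criteria are consistent with the log-likelihood
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * 4)
  expect_equal(fit$bic, -2 * fit$log_likelihood + 4 * log(fit$n_trials))
  expect_lte(fit$log_likelihood, 0)
})

test_that("fitting is deterministic given the seed and dominates the null", {
  off <- make_template_offers(1L, seed = 21L)
  off$y <- simulate_choices(off, c(alpha = 0.8, mu = 0.3, delta_plus = 0.2,
                                   delta_minus = -0.2), aa_spec, seed = 3L)
  f1 <- fit_mle(off, aa_spec, NULL, n_restarts = 5L, seed = 7L)
  f2 <- fit_mle(off, aa_spec, NULL, n_restarts = 5L, seed = 7L)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  # the coin-flip null is inside the closure of the search space
  expect_gte(f1$log_likelihood, nrow(off) * log(0.5) - 1e-6)
})

test_that("nested approach-avoidance fit dominates the prospect-theory fit", {
  off <- make_template_offers(2L, seed = 77L)
  off$y <- simulate_choices(off, c(alpha = 0.85, mu = 0.4), pt_spec,
                            seed = 13L)
  fpt <- fit_mle(off, pt_spec, NULL, n_restarts = 8L, seed = 1L)
  joint <- parse_spec_code("a0m0d1w0")
  faa <- fit_mle(off, joint, NULL, n_restarts = 8L, seed = 1L)
  expect_gte(faa$log_likelihood, fpt$log_likelihood - 1e-4)
  # delta was not in the generator, so its estimate stays small
  expect_lt(abs(faa$theta_hat["delta"]), 0.15)
})

test_that("grid oracle refines monotonically and bounds small-session fits", {
  off <- make_template_offers(1L, seed = 50L)[1:12, ]
  off$y <- simulate_choices(off, c(alpha = 0.8, mu = 0.3, delta_plus = 0.2,
                                   delta_minus = -0.2), aa_spec, seed = 4L)
  g_coarse <- grid_oracle(off, aa_spec, NULL, grid_step = 0.5)
  g_fine <- grid_oracle(off, aa_spec, NULL, grid_step = 0.25)
  expect_gte(g_fine$log_likelihood, g_coarse$log_likelihood)
  fit <- fit_mle(off, aa_spec, NULL, n_restarts = 10L, seed = 6L)
  expect_gte(fit$log_likelihood, g_fine$log_likelihood - 1e-3)
  # a single gambled trial: the argmax saturates F at 1 (likelihood is
  # monotone in F, and delta at its upper bound attains the same optimum)
  one <- data.frame(p = 0.5, O1 = 20, O2 = 0, Oc = 10, domain = "reward",
                    y = 1L)
  joint <- parse_spec_code("a0m0d1w0")
  g1 <- grid_oracle(one, joint, NULL, grid_step = 0.25)
  expect_equal(g1$log_likelihood, log(1 - 1e-9), tolerance = 1e-6)
  ll_top <- log_likelihood(c(g1$theta["alpha"], g1$theta["mu"], delta = 1),
                           joint, one)
  expect_equal(ll_top, g1$log_likelihood)
  expect_error(grid_oracle(off, aa_spec, NULL, grid_step = 0.002), "grid too large")
})

test_that("trials without a success-table cell are dropped and counted", {
  co <- make_small_cohort(n_per_group = 2L, seed = 15L)
  st <- estimate_success_table(co$trials, "group")
  # remove all level-1 cells: those trials must drop out of the offers
  st2 <- st[st$target_level != 1L, ]
  attr(st2, "mode") <- "group"
  class(st2) <- class(st)
  tr <- co$trials[co$trials$participant_id == co$trials$participant_id[1], ]
  off_full <- prepare_offers(tr, st)
  off_cut <- prepare_offers(tr, st2)
  expect_equal(nrow(off_cut) + attr(off_cut, "n_dropped"), nrow(off_full))
  expect_error(log_likelihood(c(alpha = 1, mu = 1), pt_spec, off_full[0, ]),
               "no usable trials")
})
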