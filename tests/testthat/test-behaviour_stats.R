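test_that("optimality discrepancy scores EV-maximisers and their opposites", {
  co <- make_small_cohort(n_per_group = 1L, seed = 5L)
  st <- co$surface
  pid <- co$trials$participant_id[1]
  tr <- co$trials[co$trials$participant_id == pid, ]
  off <- prepare_offers(tr, st)
  ev <- expected_values(off$p, off$O1, off$O2, off$Oc)
  opt <- as.integer(ev$ev_gamble - ev$ev_certain > 0)
  tr$choice <- opt
  expect_equal(unname(optimality_discrepancy(tr, st)), c(0, 0))
  tr$choice <- 1L - opt
  d <- optimality_discrepancy(tr, st)
  expect_equal(unname(d), c(1, 1))
  # trial order does not matter
  shuf <- tr[sample.int(nrow(tr)), ]
  expect_equal(optimality_discrepancy(shuf, st), d)
})

test_that("coin-flip choices give discrepancy near one half", {
  co <- make_small_cohort(n_per_group = 1L, seed = 6L)
  tr <- co$trials[co$trials$participant_id == co$trials$participant_id[1], ]
  big <- do.call(rbind, replicate(40, tr, simplify = FALSE))
  set.seed(2)
  big$choice <- rbinom(nrow(big), 1L, 0.5)
  d <- optimality_discrepancy(big, co$surface)
  expect_equal(unname(d), c(0.5, 0.5), tolerance = 0.06)
})

test_that("binned gamble rates use half-open bins anchored at zero", {
  co <- make_small_cohort(n_per_group = 2L, seed = 12L)
  st <- co$surface
  tr <- co$trials
  tr$choice <- 1L
  bg <- binned_gamble_rate(tr, st, n_boot = 50L)
  expect_true(all(bg$rate == 1))
  # bin centre arithmetic: value -90 with width 10 falls in [-90, -80)
  expect_equal(floor(-90 / 10) * 10 + 5, -85)
  expect_true(all(abs(bg$bin_centre %% 10) == 5))
  expect_true(all(bg$ci_low <= bg$rate & bg$rate <= bg$ci_high))
  expect_equal(sum(bg$n), nrow(tr))
})

test_that("observed bin rates calibrate against the generating model", {
  cfg <- cohort_config(n_per_age_group = c(0L, 0L, 60L, 0L, 0L, 0L),
                       seed = 33L)
  co <- generate_cohort(cfg)
  st <- co$surface
  off <- prepare_offers(co$trials, st)
  theta_by_pid <- co$participants
  f <- numeric(nrow(off))
  for (i in seq_len(nrow(theta_by_pid))) {
    sel <- off$participant_id == theta_by_pid$participant_id[i]
    th <- c(alpha = theta_by_pid$alpha[i], mu = theta_by_pid$mu[i],
            delta_plus = theta_by_pid$delta_plus[i],
            delta_minus = theta_by_pid$delta_minus[i])
    f[sel] <- gamble_prob(off[sel, ], th, aa_spec)
  }
  ev <- expected_values(off$p, off$O1, off$O2, off$Oc)
  lo <- floor((ev$ev_gamble - ev$ev_certain) / 10) * 10
  bg <- binned_gamble_rate(co$trials, st, n_boot = 50L)
  key_pred <- paste(off$age_group, off$domain, lo + 5)
  pred <- tapply(f, key_pred, mean)
  n_bin <- tapply(f, key_pred, length)
  key_obs <- paste(bg$age_group, bg$domain, bg$bin_centre)
  m <- match(key_obs, names(pred))
  ok <- bg$n >= 30
  z <- abs(bg$rate - pred[m]) / sqrt(pred[m] * (1 - pred[m]) / bg$n + 1e-12)
  expect_gt(mean(z[ok] <= 1.96, na.rm = TRUE), 0.8)
})

test_that("exponential curve fitting recovers noiseless coefficients", {
  x <- seq(-100, 100, by = 10)
  y <- -0.5 * exp(-0.02 * x) + 0.9
  f <- fit_exponential(x, y)
  expect_true(f$converged)
  expect_equal(f$a, -0.5, tolerance = 1e-6)
  expect_equal(f$b, 0.02, tolerance = 1e-6)
  expect_equal(f$c, 0.9, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # small perturbation: R-squared near but below 1
  set.seed(4)
  f2 <- fit_exponential(x, y + rnorm(length(y), 0, 0.005))
  expect_true(f2$converged)
  expect_gt(f2$r_squared, 0.98)
  expect_lt(f2$r_squared, 1)
  # constant data: degenerate, flagged via NA R-squared
  f3 <- fit_exponential(x, rep(0.7, length(x)))
  if (f3$converged) {
    expect_equal(f3$a, 0, tolerance = 1e-6)
    expect_true(is.na(f3$r_squared))
  }
})

test_that("partial Spearman matches independent small-sample oracles", {
  set.seed(10)
  n <- 10L
  x <- rnorm(n); age <- sample(1:6, n, replace = TRUE)
  z1 <- rnorm(n); z2 <- sample(1:3, n, replace = TRUE)
  r <- motorgamble:::partial_spearman_core(x, age, cbind(z1, z2))
  # oracle 1: residuals of explicit lm() on ranks
  ex <- resid(lm(rank(x) ~ rank(z1) + rank(z2)))
  ea <- resid(lm(rank(age) ~ rank(z1) + rank(z2)))
  expect_equal(r, cor(ex, ea), tolerance = 1e-10)
  # oracle 2 (single covariate): the partial-correlation recursion formula
  r1 <- motorgamble:::partial_spearman_core(x, age, cbind(z1))
  sxy <- cor(x, age, method = "spearman")
  sxz <- cor(x, z1, method = "spearman")
  syz <- cor(age, z1, method = "spearman")
  expect_equal(r1, (sxy - sxz * syz) / sqrt((1 - sxz^2) * (1 - syz^2)),
               tolerance = 1e-10)
})

test_that("partial Spearman endpoints: self-correlation and no-op covariates", {
  set.seed(11)
  n <- 200L
  age <- sample(1:6, n, replace = TRUE)
  covars <- cbind(g = rbinom(n, 1, 0.5), e = sample(1:3, n, replace = TRUE))
  # x identical to age -> residual correlation exactly 1
  r_self <- motorgamble:::partial_spearman_core(age, age, covars)
  expect_equal(r_self, 1, tolerance = 1e-12)
  # independent covariates barely move the plain Spearman estimate
  x <- rnorm(n) - 0.3 * age
  r_partial <- motorgamble:::partial_spearman_core(x, age, covars)
  r_plain <- cor(x, age, method = "spearman")
  expect_equal(r_partial, r_plain, tolerance = 0.05)
  expect_error(motorgamble:::partial_spearman_core(rep(1, n), age, covars),
               "constant")
})

test_that("bootstrap interval brackets the estimate and permutation p is valid", {
  set.seed(12)
  n <- 80L
  age <- sample(1:6, n, replace = TRUE)
  x <- -0.4 * age + rnorm(n)
  covars <- data.frame(g = rbinom(n, 1, 0.5), e = sample(1:3, n, replace = TRUE))
  for (seed in 1:3) {
    pc <- partial_spearman(x, age, covars, n_boot = 400L, n_perm = 200L,
                           seed = seed)
    expect_lte(pc$ci_low, pc$r)
    expect_gte(pc$ci_high, pc$r)
    expect_gt(pc$p, 0)
    expect_lte(pc$p, 1)
  }
  # a strong negative dependence is detected
  pc <- partial_spearman(x, age, covars, n_boot = 400L, n_perm = 400L, seed = 5)
  expect_lt(pc$r, -0.3)
  expect_lt(pc$p, 0.05)
  # determinism under the seed
  pc2 <- partial_spearman(x, age, covars, n_boot = 400L, n_perm = 400L, seed = 5)
  expect_identical(pc$ci_low, pc2$ci_low)
  expect_identical(pc$p, pc2$p)
})

test_that("estimation error follows the success-referenced formula", {
  expect_equal(estimation_error(70, 1), -30)
  expect_equal(estimation_error(0, 0), 0)
  expect_equal(estimation_error(c(70, 0), c(1, 0)), -15)
  expect_true(is.na(estimation_error(numeric(0), numeric(0))))
  # calibrated estimator: mean error approaches 0
  set.seed(13)
  p <- runif(4000, 0.1, 0.9)
  succ <- rbinom(length(p), 1, p)
  expect_equal(estimation_error(p * 100, succ), 0, tolerance = 2.5)
})
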