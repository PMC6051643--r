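test_that("value function matches the two-part power form", {
  # published worked example at alpha = 0.8
  expect_equal(round(value_fn(10, 0.8), 2), 6.31)
  expect_equal(round(value_fn(-10, 0.8), 2), -6.31)
  expect_equal(round(0.5 * value_fn(20, 0.8), 2), 5.49)
  expect_equal(round(0.5 * value_fn(-20, 0.8), 2), -5.49)
  # identity at alpha = 1, antisymmetry at lambda = 1, v(0) = 0
  O <- c(-100, -60, -20, -10, 0, 10, 20, 60, 100)
  expect_equal(value_fn(O, 1), O)
  expect_equal(value_fn(O, 0.63), -value_fn(-O, 0.63))
  expect_equal(value_fn(0, 0), 0)
  # lambda scales losses only
  expect_equal(value_fn(-10, 0.8, lambda = 2), 2 * value_fn(-10, 0.8))
  expect_equal(value_fn(10, 0.8, lambda = 2), value_fn(10, 0.8))
})

test_that("probability weighting is the one-parameter log-log form", {
  p <- c(0.05, 0.2, 0.5, 0.9, 1)
  expect_equal(weight_prob(p, 1), p)          # gamma = 1 is identity
  expect_equal(weight_prob(p, NULL), p)       # linear model passes through
  expect_equal(weight_prob(1, 2), 1)
  expect_equal(weight_prob(0, 0.5), 0)
  # independent evaluation of w(0.5) at gamma = 0.5
  expect_equal(weight_prob(0.5, 0.5), exp(-sqrt(log(2))), tolerance = 1e-12)
  expect_equal(weight_prob(0.5, 0.5), 0.4348, tolerance = 1e-3)
  # monotone increasing in p
  for (g in c(0.4, 1, 2.5)) expect_true(all(diff(weight_prob(p, g)) > 0))
})

test_that("the model family enumerates 24 variants with stable codes", {
  specs <- enumerate_models()
  expect_length(specs, 24L)
  expect_equal(anyDuplicated(names(specs)), 0L)
  # winning approach-avoidance model [alpha, mu, delta+, delta-] is ID 10,
  # prospect-theory winner [alpha+, alpha-, mu+, mu-] is ID 4
  expect_equal(names(specs)[10], "a0m0d2w0")
  expect_equal(specs[[10]]$par_names,
               c("alpha", "mu", "delta_plus", "delta_minus"))
  expect_equal(names(specs)[4], "a1m1d0w0")
  expect_equal(specs[[4]]$par_names,
               c("alpha_plus", "alpha_minus", "mu_plus", "mu_minus"))
  # 12 linear-weighting variants; parameter counts consistent with flags
  expect_equal(sum(vapply(specs, function(s) s$weighting == "linear",
                          logical(1))), 12L)
  expect_equal(model_spec()$k, 2L)
  ks <- vapply(specs, `[[`, numeric(1), "k")
  expect_true(all(ks >= 2 & ks <= 7))
  # codes round-trip through the parser
  for (s in specs) expect_equal(parse_spec_code(s$code)$par_names, s$par_names)
  expect_error(parse_spec_code("a2m0d0w0"), "malformed")
})

test_that("gamble probability follows softmax plus clamped Pavlovian offset", {
  # an offer with equal utilities: p * v(O1) = v(Oc) at alpha = 1
  off <- data.frame(p = 0.5, O1 = 20, O2 = 0, Oc = 10, domain = "reward")
  expect_equal(gamble_prob(off, c(alpha = 1, mu = 2), pt_spec), 0.5)
  joint <- parse_spec_code("a0m0d1w0")
  expect_equal(gamble_prob(off, c(alpha = 1, mu = 2, delta = 0.2), joint), 0.7)
  # saturated softmax plus a large offset clamps to exactly 1
  big <- data.frame(p = 1, O1 = 100, O2 = 0, Oc = 10, domain = "reward")
  expect_equal(gamble_prob(big, c(alpha = 1, mu = 10, delta = 0.7), joint), 1)
  # the offset itself is added after the softmax, never clamped first
  neg <- data.frame(p = 0, O1 = 20, O2 = 0, Oc = 10, domain = "reward")
  expect_equal(gamble_prob(neg, c(alpha = 1, mu = 10, delta = -0.9), joint), 0)
  expect_error(gamble_prob(off, c(alpha = 1.4, mu = 2), pt_spec), "bounds")
})

test_that("null restriction alpha = mu = delta = 0 predicts 0.5 everywhere", {
  surf <- sample_success_surface(cohort_config())
  off <- make_template_offers(1L)
  f <- gamble_prob(off, c(alpha = 0, mu = 0, delta = 0),
                   parse_spec_code("a0m0d1w0"),
                   check = FALSE)
  expect_equal(f, rep(0.5, nrow(off)))
})

test_that("gamble probability is monotone in O1, delta, and Oc", {
  th <- c(alpha = 0.8, mu = 0.5, delta = 0.1)
  joint <- parse_spec_code("a0m0d1w0")
  o1 <- data.frame(p = 0.6, O1 = seq(10, 100, 10), O2 = 0, Oc = 10,
                   domain = "reward")
  expect_true(all(diff(gamble_prob(o1, th, joint)) >= 0))
  oc <- data.frame(p = 0.6, O1 = 60, O2 = 0, Oc = seq(1, 50, 5),
                   domain = "reward")
  expect_true(all(diff(gamble_prob(oc, th, joint)) <= 0))
  one <- data.frame(p = 0.6, O1 = 20, O2 = 0, Oc = 10, domain = "reward")
  fd <- vapply(seq(-0.5, 0.5, 0.1), function(d) {
    gamble_prob(one, c(alpha = 0.8, mu = 0.5, delta = d), joint)
  }, numeric(1))
  expect_true(all(diff(fd) >= 0))
})

test_that("zero joint delta reproduces the nested prospect-theory model", {
  off <- make_template_offers(1L)
  th_pt <- c(alpha = 0.75, mu = 0.4)
  th_aa <- c(alpha = 0.75, mu = 0.4, delta = 0)
  expect_equal(gamble_prob(off, th_aa, parse_spec_code("a0m0d1w0")),
               gamble_prob(off, th_pt, pt_spec))
})

test_that("split deltas with delta+ > 0 > delta- open a reward-punishment gap", {
  # matched offers with EV difference exactly 0 in both domains
  off <- data.frame(p = 0.5, O1 = c(20, 0), O2 = c(0, -20), Oc = c(10, -10),
                    domain = c("reward", "punishment"))
  th <- c(alpha = 0.8, mu = 0.5, delta_plus = 0.25, delta_minus = -0.25)
  f <- gamble_prob(off, th, aa_spec)
  expect_gt(f[1], f[2])
  # without the offsets, alpha < 1 predicts the reverse ordering at EV = 0
  f0 <- gamble_prob(off, c(alpha = 0.8, mu = 0.5), pt_spec)
  expect_lt(f0[1], f0[2])
})

test_that("domain-split parameters select by trial domain", {
  off <- data.frame(p = 0.5, O1 = c(20, 0), O2 = c(0, -20), Oc = c(10, -10),
                    domain = c("reward", "punishment"))
  spec <- parse_spec_code("a1m1d0w0")
  th <- c(alpha_plus = 1, alpha_minus = 1, mu_plus = 10, mu_minus = 1e-6)
  f <- gamble_prob(off, th, spec)
  # punishment trial gets the near-zero temperature -> indifference
  expect_equal(f[2], 0.5, tolerance = 1e-4)
  # reward trial at alpha = 1, p = 0.5 is exactly utility-matched
  expect_equal(f[1], 0.5)
  # a decisive reward offer under the sharp reward temperature saturates
  off2 <- data.frame(p = 0.9, O1 = 20, O2 = 0, Oc = 10, domain = "reward")
  expect_gt(gamble_prob(off2, th, spec), 0.99)
})
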