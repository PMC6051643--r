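## Model-free behavioural statistics: optimality discrepancy, binned
## gamble-rate curves with exponential fits, partial Spearman correlations
## with BCa bootstrap intervals and permutation p-values, and the
## estimation-error metric of the probability-estimation control study.

#' Optimality discrepancy of a participant's choices
#'
#' The optimal decision on a trial is to gamble when
#' `EV_gamble - EV_certain > 0` and to skip when it is negative; the
#' discrepancy is the mean absolute difference between the observed choice and
#' the optimal one, computed separately for reward and punishment trials.
#' Trials with an EV difference of exactly 0 are excluded (either action is
#' optimal). 0 marks an ideal expected-value maximiser, 1 a systematic
#' anti-maximiser.
#'
#' @param trials One participant's trial rows.
#' @param success_table Success table for EV computation.
#' @return Named numeric vector `c(reward = ..., punishment = ...)`; a domain
#'   with no resolvable trials is `NA`.
#' @export
optimality_discrepancy <- function(trials, success_table) {
  offers <- prepare_offers(trials, success_table)
  ev <- expected_values(offers$p, offers$O1, offers$O2, offers$Oc)
  evd <- ev$ev_gamble - ev$ev_certain
  keep <- evd != 0
  opt <- as.integer(evd > 0)
  out <- c(reward = NA_real_, punishment = NA_real_)
  for (d in names(out)) {
    sel <- keep & offers$domain == d
    if (any(sel)) out[d] <- mean(abs(offers$y[sel] - opt[sel]))
  }
  out
}

#' Observed gamble rate binned by expected-value difference
#'
#' Groups trials into half-open bins `[lo, lo + width)` of
#' `EV_gamble - EV_certain` anchored at 0 and reports the observed gamble
#' proportion per (age group, domain, bin) with percentile bootstrap 95%
#' intervals over trials. Empty bins are absent from the output.
#'
#' @param trials Cohort trial table.
#' @param success_table Success table for EV computation.
#' @param bin_width Bin width in points (default 10).
#' @param n_boot Bootstrap replicates per bin (default 500).
#' @param seed Seed for the bootstrap.
#' @return Data frame with `age_group`, `domain`, `bin_centre`, `rate`, `n`,
#'   `ci_low`, `ci_high`.
#' @export
binned_gamble_rate <- function(trials, success_table, bin_width = 10,
                               n_boot = 500L, seed = 1L) {
  stopifnot(bin_width > 0)
  offers <- prepare_offers(trials, success_table)
  ev <- expected_values(offers$p, offers$O1, offers$O2, offers$Oc)
  evd <- ev$ev_gamble - ev$ev_certain
  lo <- floor(evd / bin_width) * bin_width
  key <- paste(offers$age_group, offers$domain, format(lo, trim = TRUE), sep = "|")
  groups <- split(offers$y, key)
  meta <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
  out <- data.frame(
    age_group = as.integer(meta[, 1]),
    domain = meta[, 2],
    bin_centre = as.numeric(meta[, 3]) + bin_width / 2,
    rate = vapply(groups, mean, numeric(1)),
    n = vapply(groups, length, integer(1)),
    stringsAsFactors = FALSE
  )
  ci <- with_seed(seed, t(vapply(groups, function(y) {
    bm <- vapply(seq_len(n_boot), function(i) mean(sample(y, replace = TRUE)),
                 numeric(1))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }, numeric(2))))
  out$ci_low <- ci[, 1]
  out$ci_high <- ci[, 2]
  rownames(out) <- NULL
  out[order(out$age_group, out$domain, out$bin_centre), ]
}

#' Fit a three-parameter exponential to a binned curve
#'
#' Nonlinear least squares of `y = a exp(-b x) + c` with `b >= 0`, as used to
#' summarise gamble-rate curves against the expected-value difference.
#' Initialisation: `c` at the mean of the last two points, `a` at the first
#' point's residual from `c`, `b = 0.01`.
#'
#' @param x Bin centres.
#' @param y Rates.
#' @return A list `a`, `b`, `c`, `r_squared`, `converged`. On non-convergence
#'   or a degenerate (constant) input, `converged = FALSE` and parameters are
#'   `NA`; for constant data `r_squared` is `NA` (flagged degenerate).
#' @export
fit_exponential <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  ss_tot <- sum((y - mean(y))^2)
  c0 <- mean(utils::tail(y, 2))
  a0 <- y[1] - c0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
                      start = list(a = a0, b = 0.01, c = c0),
                      lower = c(a = -Inf, b = 0, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                r_squared = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * length(y)) NA_real_ else 1 - ss_res / ss_tot
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       r_squared = r2, converged = TRUE)
}

## Core partial Spearman statistic: correlation between the residuals of the
## rank-transformed x and age after least-squares regression on the
## rank-transformed covariates.
partial_spearman_core <- function(x, age, covars) {
  Z <- cbind(1, apply(as.matrix(covars), 2, rank))
  rx <- rank(x); ra <- rank(age)
  ex <- stats::lm.fit(Z, rx)$residuals
  ea <- stats::lm.fit(Z, ra)$residuals
  # ranks are O(n), so residual sds below n * 1e-10 are numerically zero
  if (stats::sd(ex) < length(ex) * 1e-10 || stats::sd(ea) < length(ea) * 1e-10) {
    stop("constant variable after rank residualisation; correlation undefined")
  }
  stats::cor(ex, ea)
}

#' Partial Spearman correlation with BCa bootstrap CI and permutation p
#'
#' Rank-transforms `x`, `age` and the covariates, residualises the ranks of
#' `x` and `age` on the covariate ranks by least squares, and correlates the
#' residuals. The 95% confidence interval is a bias-corrected and accelerated
#' (BCa) bootstrap over participants; the two-sided p-value comes from
#' permuting the age labels, with the add-one correction
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param x Numeric outcome per participant.
#' @param age Ordinal age-group codes.
#' @param covars Data frame/matrix of controlling variables (e.g. gender and
#'   education codes, treated as ordinal ranks).
#' @param n_boot Bootstrap resamples (study default 10000).
#' @param n_perm Permutations (study default 10000).
#' @param seed Integer seed.
#' @return A list of class `partial_corr`: `r`, `ci_low`, `ci_high`, `p`,
#'   `n`, `n_boot`, `n_perm`.
#' @export
partial_spearman <- function(x, age, covars, n_boot = 10000L, n_perm = 10000L,
                             seed = 1L) {
  stopifnot(length(x) == length(age), nrow(as.matrix(covars)) == length(x),
            n_boot >= 1L, n_perm >= 1L)
  covars <- as.data.frame(covars)
  r_obs <- partial_spearman_core(x, age, covars)
  dat <- cbind(x = x, age = age, as.matrix(covars))
  ci <- with_seed(derive_seed(seed, "boot"), {
    bt <- boot::boot(dat, function(d, idx) {
      partial_spearman_core(d[idx, 1], d[idx, 2], d[idx, -(1:2), drop = FALSE])
    }, R = n_boot)
    out <- tryCatch(boot::boot.ci(bt, type = "bca")$bca[4:5],
                    error = function(e) rep(NA_real_, 2))
    out
  })
  p <- with_seed(derive_seed(seed, "perm"), {
    n <- length(age)
    r_perm <- vapply(seq_len(n_perm), function(i) {
      partial_spearman_core(x, age[sample.int(n)], covars)
    }, numeric(1))
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  })
  structure(
    list(r = r_obs, ci_low = ci[1], ci_high = ci[2], p = p,
         n = length(x), n_boot = n_boot, n_perm = n_perm),
    class = "partial_corr"
  )
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial Spearman r = %.3f, 95%% CI [%.3f, %.3f], p = %.4g (n = %d)\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Probability-estimation error of the control study
#'
#' On each estimation trial the error is `estimate - 100` if the motor action
#' succeeded and `estimate - 0` if it failed; a well-calibrated estimator has
#' mean error near 0.
#'
#' @param estimate Verbal estimates in percent (multiples of 10 in the task).
#' @param success 0/1 motor success indicator.
#' @return Mean error in percent; `NA` for empty input.
#' @export
estimation_error <- function(estimate, success) {
  stopifnot(length(estimate) == length(success))
  if (length(estimate) == 0L) return(NA_real_)
  mean(estimate - 100 * success)
}
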