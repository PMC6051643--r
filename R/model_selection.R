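## Information criteria, pseudo-R2 against the coin-flip null, subject-level
## model comparison, and per-individual likelihood-ratio tests.

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 logL + 2k`; `BIC = -2 logL + k ln(N)`.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param N Number of data points (trials).
#' @return The criterion value.
#' @export
aic <- function(logL, k) {
  stopifnot(k >= 0)
  -2 * logL + 2 * k
}

#' @rdname aic
#' @export
bic <- function(logL, k, N) {
  stopifnot(k >= 0, N >= 1)
  -2 * logL + k * log(N)
}

#' McFadden-style pseudo-R2 against the random-choice null
#'
#' The null model restricts `alpha = mu = delta = 0`, which forces a gamble
#' probability of 0.5 on every trial, hence a null log-likelihood of
#' `N ln(0.5)`. Returns `1 - logL_model / (N ln 0.5)`.
#'
#' @param logL_model Maximised log-likelihood of the fitted model.
#' @param N Number of trials.
#' @return Pseudo-R2 (0 for a model no better than chance, 1 for perfect fit).
#' @export
pseudo_r2 <- function(logL_model, N) {
  stopifnot(N >= 1)
  1 - logL_model / (N * log(0.5))
}

#' Likelihood-ratio test for nested models
#'
#' Statistic `2 (logL_alt - logL_null)` referred to a chi-square distribution
#' with `df` degrees of freedom. Small negative statistics (within
#' `tolerance`, from optimiser noise) are clipped to 0; larger ones signal a
#' non-nested or mis-fitted pair and raise an error.
#'
#' @param logL_null,logL_alt Maximised log-likelihoods of the nested (null)
#'   and nesting (alternative) models.
#' @param df Degrees-of-freedom difference (>= 1).
#' @param tolerance Permitted optimiser slack (default 1e-6).
#' @return Upper-tail p-value.
#' @export
lr_test <- function(logL_null, logL_alt, df, tolerance = 1e-6) {
  stopifnot(df >= 1)
  stat <- 2 * (logL_alt - logL_null)
  if (stat < -2 * tolerance) {
    stop("alternative log-likelihood below null beyond tolerance; models not nested or fit failed")
  }
  stat <- max(stat, 0)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Subject-level model comparison report
#'
#' Sums AIC and BIC over participants for every model, identifies the
#' smallest-summed-BIC (and -AIC) model, tallies for each alternative the
#' percentage of participants better fitted by the winner versus the
#' alternative (exact per-subject ties contribute half to each side), and runs
#' two-sided paired t-tests of the winner's per-subject criterion values
#' against every alternative with Bonferroni correction.
#'
#' Criterion ties between models are broken toward the smaller parameter
#' count, then lexicographically by spec code. Participants missing a fit for
#' some model are excluded pairwise, with a warning.
#'
#' @param fits Cohort fit table from [fit_cohort()] (columns
#'   `participant_id`, `code`, `k`, `aic`, `bic` required).
#' @return A list of class `comparison_report`: `summed` (data frame of per-
#'   model summed criteria), `winner_bic`, `winner_aic` (spec codes),
#'   `winners` (per-alternative winner percentages and Bonferroni-corrected
#'   paired-test p-values for both criteria).
#' @export
compare_models <- function(fits) {
  codes <- unique(fits$code)
  k_of <- vapply(codes, function(cd) fits$k[fits$code == cd][1], numeric(1))
  full <- stats::aggregate(cbind(aic, bic) ~ code, data = fits, FUN = sum)
  n_per <- table(fits$code)
  if (length(unique(n_per)) > 1L) {
    warning("unequal fit counts across models; pairwise exclusion applied")
  }
  pick_winner <- function(crit) {
    v <- full[[crit]]
    # tolerance-based tie detection: summed criteria that differ only by
    # floating-point accumulation order count as tied
    cand <- full$code[v - min(v) <= 1e-8 * max(1, abs(min(v)))]
    if (length(cand) > 1L) {
      cand <- cand[order(k_of[cand], cand)]
    }
    cand[1]
  }
  winner_bic <- pick_winner("bic")
  winner_aic <- pick_winner("aic")

  crit_matrix <- function(crit) {
    m <- stats::reshape(fits[, c("participant_id", "code", crit)],
                        idvar = "participant_id", timevar = "code",
                        direction = "wide")
    colnames(m) <- sub(paste0("^", crit, "\\."), "", colnames(m))
    m
  }
  tally <- function(crit, winner) {
    wide <- crit_matrix(crit)
    alts <- setdiff(codes, winner)
    res <- lapply(alts, function(alt) {
      ok <- stats::complete.cases(wide[, c(winner, alt)])
      w <- wide[[winner]][ok]; a <- wide[[alt]][ok]
      n <- length(w)
      wins <- sum(w < a) + 0.5 * sum(w == a)
      p <- if (n >= 2L && stats::sd(w - a) > 0) {
        stats::t.test(w, a, paired = TRUE)$p.value
      } else NA_real_
      data.frame(alternative = alt, criterion = crit, n = n,
                 pct_winner = 100 * wins / n,
                 pct_alternative = 100 * (n - wins) / n,
                 p_paired = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_bonferroni <- pmin(out$p_paired * length(alts), 1)
    out
  }
  winners <- rbind(tally("bic", winner_bic), tally("aic", winner_aic))
  structure(
    list(summed = full, winner_bic = winner_bic, winner_aic = winner_aic,
         winners = winners),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Summed-BIC winner:", x$winner_bic,
      "| summed-AIC winner:", x$winner_aic, "\n")
  s <- x$summed[order(x$summed$bic), ]
  print(utils::head(s, 5), row.names = FALSE)
  invisible(x)
}

#' Per-individual likelihood-ratio tally for joint versus split parameters
#'
#' For each participant and each key parameter (`delta`, `alpha`, `mu`),
#' compares the fit of the base model with the parameter joint against the
#' model with it split by domain (df = 1) and counts participants for whom
#' the split is significant at `level`. The delta comparison is run on top of
#' the joint-alpha/joint-mu approach-avoidance pair; the alpha and mu
#' comparisons on top of the winning split-delta model.
#'
#' @param fits Cohort fit table covering the involved spec codes.
#' @param level Significance level (default 0.05).
#' @return Data frame with columns `parameter`, `null_code`, `alt_code`,
#'   `n_tested`, `n_significant`.
#' @export
lr_split_tally <- function(fits, level = 0.05) {
  pairs <- list(
    delta = c("a0m0d1w0", "a0m0d2w0"),
    alpha = c("a0m0d2w0", "a1m0d2w0"),
    mu = c("a0m0d2w0", "a0m1d2w0")
  )
  rows <- lapply(names(pairs), function(par) {
    nc <- pairs[[par]][1]; ac <- pairs[[par]][2]
    nl <- fits[fits$code == nc, c("participant_id", "logL")]
    al <- fits[fits$code == ac, c("participant_id", "logL")]
    m <- merge(nl, al, by = "participant_id", suffixes = c("_null", "_alt"))
    pv <- mapply(function(l0, l1) lr_test(l0, l1, df = 1, tolerance = 1e-3),
                 m$logL_null, pmax(m$logL_alt, m$logL_null))
    data.frame(parameter = par, null_code = nc, alt_code = ac,
               n_tested = nrow(m), n_significant = sum(pv < level),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
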