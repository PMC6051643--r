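## Recovery diagnostics: can the fitted parameters be trusted (parameter
## recovery), is the winning model identifiable from data it generated (model
## recovery), and do fitted models reproduce the behavioural curves
## (falsification by predicted curves)?

#' Parameter recovery for "typical participant" parameter sets
#'
#' For each generating parameter set, simulates `n_sims` choice sequences on
#' the template offers, refits the model, and summarises the cloud of
#' recovered parameters (median and central 80% interval) against truth.
#'
#' @param param_sets Named list of named parameter vectors (each satisfying
#'   `spec`).
#' @param spec Generating/fitting `model_spec`.
#' @param n_sims Simulations per parameter set (study default 50).
#' @param template_offers Offer table (columns `p`, `O1`, `O2`, `Oc`,
#'   `domain`) defining the trial design, e.g. from [prepare_offers()] or a
#'   schedule joined to a success surface.
#' @param n_restarts Restarts per refit.
#' @param seed Master seed.
#' @return A list of class `recovery_report`: `draws` (long data frame:
#'   `set`, `sim`, parameter columns), `summary` (per set x parameter:
#'   `truth`, `median`, `q10`, `q90`, `covered` = truth inside the central
#'   80% interval).
#' @export
parameter_recovery <- function(param_sets, spec, n_sims, template_offers,
                               n_restarts = 10L, seed = 1L) {
  stopifnot(n_sims >= 1L)
  if (is.null(names(param_sets))) names(param_sets) <- paste0("set", seq_along(param_sets))
  draws <- list()
  for (sname in names(param_sets)) {
    truth <- param_sets[[sname]]
    for (s in seq_len(n_sims)) {
      sim_seed <- derive_seed(seed, paste(sname, s))
      off <- template_offers
      off$y <- simulate_choices(off, truth, spec, seed = sim_seed)
      off$participant_id <- paste(sname, s)
      fit <- fit_mle(off, spec, NULL, n_restarts = n_restarts, seed = sim_seed)
      draws[[length(draws) + 1L]] <- data.frame(
        set = sname, sim = s, t(fit$theta_hat), stringsAsFactors = FALSE
      )
    }
  }
  draws <- do.call(rbind, draws)
  summ <- list()
  for (sname in names(param_sets)) {
    truth <- param_sets[[sname]]
    d <- draws[draws$set == sname, , drop = FALSE]
    for (p in spec$par_names) {
      q <- stats::quantile(d[[p]], c(0.1, 0.5, 0.9), names = FALSE)
      summ[[length(summ) + 1L]] <- data.frame(
        set = sname, parameter = p, truth = unname(truth[[p]]),
        median = q[2], q10 = q[1], q90 = q[3],
        covered = truth[[p]] >= q[1] & truth[[p]] <= q[3],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(draws = draws, summary = do.call(rbind, summ)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Model recovery between the prospect-theory and approach-avoidance winners
#'
#' Simulates cohorts under each generating model and refits both candidate
#' models to every simulated participant; the summed-BIC winner is tallied per
#' cohort. Cohorts are generated via [generate_cohort()]: the approach-
#' avoidance generator uses the config's Pavlovian profiles, the prospect-
#' theory generator sets them to zero and is scored against the delta-free
#' candidate.
#'
#' @param config A [cohort_config()]; `n_per_age_group` controls cohort size.
#' @param n_cohorts Cohorts per generator.
#' @param n_restarts Restarts per fit.
#' @param seed Master seed.
#' @return Data frame of confusion counts: `generator`, `winner`, `count`.
#' @export
model_recovery <- function(config, n_cohorts = 1L, n_restarts = 10L, seed = 1L) {
  aa <- parse_spec_code("a0m0d2w0")
  pt <- parse_spec_code("a0m0d0w0")
  candidates <- list(aa, pt)
  pt_config <- config
  pt_config$delta_plus_anchors <- c(0, 0)
  pt_config$delta_minus_anchors <- c(0, 0)
  pt_config$delta_sd <- 0
  gens <- list(AA = config, PT = pt_config)
  rows <- list()
  for (gname in names(gens)) {
    wins <- c(a0m0d2w0 = 0L, a0m0d0w0 = 0L)
    for (cidx in seq_len(n_cohorts)) {
      g <- gens[[gname]]
      g$seed <- derive_seed(seed, paste(gname, cidx))
      cohort <- generate_cohort(g)
      st <- estimate_success_table(cohort$trials, "group")
      fits <- fit_cohort(cohort$trials, st, specs = candidates,
                         n_restarts = n_restarts, seed = g$seed)
      rep <- compare_models(fits)
      wins[rep$winner_bic] <- wins[rep$winner_bic] + 1L
    }
    rows[[gname]] <- data.frame(generator = gname, winner = names(wins),
                                count = as.integer(wins),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-predicted gamble-probability curves
#'
#' For every trial, computes the fitted model's predicted gamble probability
#' for that participant and averages predictions within (age group, domain,
#' expected-value-difference bin). Overlaying these curves on the observed
#' [binned_gamble_rate()] curves is the model-falsification check: only
#' split-delta models can produce a reward-above-punishment gap where
#' `EV_gamble - EV_certain` is near 0.
#'
#' @param fits Cohort fit table restricted to one spec code (or containing a
#'   `code` column from which `spec_code` is selected).
#' @param trials Cohort trial table.
#' @param success_table Success table for offer resolution.
#' @param spec_code Code of the model whose predictions to compute.
#' @param bin_width Width of the EV-difference bins in points (default 10).
#' @return Data frame with `age_group`, `domain`, `bin_centre`,
#'   `predicted_rate`, `n`.
#' @export
predicted_curves <- function(fits, trials, success_table,
                             spec_code = "a0m0d2w0", bin_width = 10) {
  stopifnot(bin_width > 0)
  spec <- parse_spec_code(spec_code)
  f <- fits[fits$code == spec_code, , drop = FALSE]
  if (nrow(f) == 0L) stop("no fits for spec code ", spec_code)
  offers <- prepare_offers(trials, success_table)
  pred <- rep(NA_real_, nrow(offers))
  for (i in seq_len(nrow(f))) {
    sel <- offers$participant_id == f$participant_id[i]
    if (!any(sel)) next
    theta <- stats::setNames(as.numeric(f[i, spec$par_names]), spec$par_names)
    pred[sel] <- gamble_prob(offers[sel, , drop = FALSE], theta, spec)
  }
  ev <- expected_values(offers$p, offers$O1, offers$O2, offers$Oc)
  evd <- ev$ev_gamble - ev$ev_certain
  lo <- floor(evd / bin_width) * bin_width
  keep <- !is.na(pred)
  agg <- stats::aggregate(
    pred[keep],
    by = list(age_group = offers$age_group[keep],
              domain = offers$domain[keep],
              bin_centre = lo[keep] + bin_width / 2),
    FUN = mean
  )
  cnt <- stats::aggregate(
    pred[keep],
    by = list(age_group = offers$age_group[keep],
              domain = offers$domain[keep],
              bin_centre = lo[keep] + bin_width / 2),
    FUN = length
  )
  names(agg)[4] <- "predicted_rate"
  agg$n <- cnt$x
  agg[order(agg$age_group, agg$domain, agg$bin_centre), ]
}
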