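## Per-participant maximum-likelihood estimation: Bernoulli log-likelihood of
## the choice sequence, bounded multi-start optimisation, and an exhaustive
## grid oracle used for verification.

#' Resolve a participant's trials into gamble offers
#'
#' Attaches the success probability from a success table and renames payoff
#' columns into the `(p, O1, O2, Oc)` offer form used by [gamble_prob()].
#' Trials whose success-table cell is missing are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param trials Trial rows for one or more participants.
#' @param success_table A `success_table`.
#' @return A data frame with columns `participant_id`, `p`, `O1`, `O2`, `Oc`,
#'   `domain`, `y` (choice, if present), `age_group`; attribute `n_dropped`.
#' @export
prepare_offers <- function(trials, success_table) {
  p <- lookup_success(success_table, trials)
  keep <- !is.na(p)
  out <- data.frame(
    participant_id = trials$participant_id[keep],
    age_group = trials$age_group[keep],
    p = p[keep],
    O1 = trials$success_value[keep],
    O2 = trials$fail_value[keep],
    Oc = trials$certain_value[keep],
    domain = trials$domain[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(trials$choice)) out$y <- trials$choice[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Choice log-likelihood of a parameter vector
#'
#' `sum_i y_i log F_i + (1 - y_i) log(1 - F_i)` where `F_i` is the model
#' gamble probability on trial `i`. Because the Pavlovian clamp permits `F`
#' exactly 0 or 1, `F` is clamped into `[eps, 1 - eps]` inside the logarithms
#' only.
#'
#' @param theta Named parameter vector.
#' @param spec A `model_spec`.
#' @param offers Offers with a choice column `y` (see [prepare_offers()]).
#' @param eps Log-clamping constant (default 1e-9).
#' @param check Validate parameter bounds.
#' @return The log-likelihood (always <= 0).
#' @export
log_likelihood <- function(theta, spec, offers, eps = 1e-9, check = TRUE) {
  if (nrow(offers) == 0L) stop("no usable trials: all success probabilities missing")
  f <- gamble_prob(offers, theta, spec, check = check)
  fe <- pmin(pmax(f, eps), 1 - eps)
  sum(offers$y * log(fe) + (1 - offers$y) * log(1 - fe))
}

## Specialised negative-log-likelihood closure for the optimiser: the offer
## constants and per-trial parameter indices are resolved once, so each
## evaluation is a handful of vector operations. Algebraically identical to
## -log_likelihood() (lambda fixed at 1: sign(O) * |O|^alpha, with sign(0)=0
## giving v(0)=0 for free).
make_nll <- function(offers, spec, eps = 1e-9) {
  y <- offers$y
  p <- offers$p
  is_pun <- offers$domain == "punishment"
  aO1 <- abs(offers$O1); sO1 <- sign(offers$O1)
  aO2 <- abs(offers$O2); sO2 <- sign(offers$O2)
  aOc <- abs(offers$Oc); sOc <- sign(offers$Oc)
  pn <- spec$par_names
  idx <- function(base, split) {
    if (split) ifelse(is_pun, match(paste0(base, "_minus"), pn),
                      match(paste0(base, "_plus"), pn))
    else rep.int(match(base, pn), length(y))
  }
  i_alpha <- idx("alpha", spec$alpha_split)
  i_mu <- idx("mu", spec$mu_split)
  i_delta <- switch(spec$delta_mode, none = NULL, joint = idx("delta", FALSE),
                    split = idx("delta", TRUE))
  i_gamma <- if (spec$weighting == "weighted") match("gamma", pn) else NULL
  log1me <- log(1 - eps)
  function(v) {
    a <- v[i_alpha]
    wp <- if (is.null(i_gamma)) p else {
      w <- exp(-(-log(p))^v[i_gamma]); w[p == 0] <- 0; w
    }
    u <- wp * sO1 * aO1^a + (1 - wp) * sO2 * aO2^a - sOc * aOc^a
    f <- 1 / (1 + exp(-v[i_mu] * u))
    if (!is.null(i_delta)) f <- pmin(pmax(f + v[i_delta], 0), 1)
    fe <- pmin(pmax(f, eps), 1 - eps)
    -sum(y * log(fe) + (1 - y) * log(1 - fe))
  }
}

#' Fit a model to one participant's choices by multi-start bounded MLE
#'
#' Runs bounded quasi-Newton (`L-BFGS-B`) local searches from `n_restarts`
#' starting points drawn uniformly within the parameter bounds and keeps the
#' best. The RNG stream is derived from `(seed, participant id)` so cohort
#' fits are reproducible regardless of fitting order.
#'
#' @param trials One participant's trial rows (or ready-made offers carrying a
#'   `y` column, in which case `success_table` may be `NULL`).
#' @param spec A `model_spec`.
#' @param success_table Success-probability table used to resolve offers.
#' @param n_restarts Number of random starting points (study default 200;
#'   smaller values are adequate for the 42-trial design and used in examples).
#' @param seed Integer master seed.
#' @return A list of class `fit_result`: `spec`, `theta_hat`, `log_likelihood`,
#'   `n_trials`, `n_dropped`, `aic`, `bic`, `pseudo_r2`, `n_restarts`,
#'   `converged`.
#' @export
fit_mle <- function(trials, spec, success_table = NULL, n_restarts = 200L,
                    seed = 1L) {
  stopifnot(n_restarts >= 1L)
  offers <- if (is.null(success_table)) trials else
    prepare_offers(trials, success_table)
  if (is.null(offers$y)) stop("trials carry no choice column")
  pid <- offers$participant_id[1] %||% "session"
  b <- par_bounds(spec)
  nll <- make_nll(offers, spec)
  k <- spec$k
  starts <- with_seed(derive_seed(seed, pid), {
    matrix(stats::runif(n_restarts * k, rep(b$lower, each = n_restarts),
                        rep(b$upper, each = n_restarts)),
           nrow = n_restarts, ncol = k)
  })
  # The clamped likelihood is flat wherever the softmax saturates (large mu,
  # extreme delta), so purely random starts can all land where the gradient
  # vanishes. Two fixed well-scaled starts (moderate/low temperature, zero
  # offset) are always searched in addition to the random ones.
  fixed <- vapply(spec$par_names, function(p) {
    switch(sub("_(plus|minus)$", "", p),
           alpha = c(0.5, 0.8), mu = c(0.3, 0.05), delta = c(0, 0),
           gamma = c(1, 1))
  }, numeric(2))
  starts <- rbind(starts, matrix(fixed, nrow = 2))
  best <- NULL
  converged <- FALSE
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[r, ], nll, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper),
      error = function(e) list(par = starts[r, ], value = nll(starts[r, ]),
                               convergence = 99L)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0L) converged <- TRUE
  }
  theta_hat <- stats::setNames(best$par, spec$par_names)
  ll <- -best$value
  n <- nrow(offers)
  structure(
    list(spec = spec, theta_hat = theta_hat, log_likelihood = ll,
         n_trials = n, n_dropped = attr(offers, "n_dropped") %||% 0L,
         aic = aic(ll, k), bic = bic(ll, k, n), pseudo_r2 = pseudo_r2(ll, n),
         n_restarts = n_restarts, converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result [", x$spec$code, "] logL =", format(x$log_likelihood),
      " BIC =", format(x$bic), "\n")
  print(round(x$theta_hat, 4))
  invisible(x)
}

#' Exhaustive grid-search oracle for the likelihood surface
#'
#' Evaluates the log-likelihood on a regular grid over the bounded parameter
#' box (`seq(lower, upper, by = grid_step)` per parameter) and returns the
#' argmax. Intended as an independent check on [fit_mle()], not as a fitting
#' routine; refuses grids above 1e7 points.
#'
#' @inheritParams fit_mle
#' @param grid_step Grid spacing applied to every parameter.
#' @return A list with `theta` (named vector at the grid argmax),
#'   `log_likelihood`, and `n_grid`.
#' @export
grid_oracle <- function(trials, spec, success_table = NULL, grid_step = 0.1) {
  offers <- if (is.null(success_table)) trials else
    prepare_offers(trials, success_table)
  if (spec$k > 4L) stop("grid oracle supports at most 4 free parameters")
  b <- par_bounds(spec)
  axes <- lapply(spec$par_names, function(p) {
    s <- seq(b$lower[p], b$upper[p], by = grid_step)
    if (s[length(s)] < b$upper[p]) s <- c(s, b$upper[p])
    s
  })
  n_grid <- prod(vapply(axes, length, integer(1)))
  if (n_grid > 1e7) stop("grid too large (", n_grid, " points); coarsen grid_step")
  grid <- do.call(expand.grid, stats::setNames(axes, spec$par_names))
  ll <- numeric(n_grid)
  eps <- 1e-9
  is_pun <- offers$domain == "punishment"
  for (i in seq_len(nrow(offers))) {
    par <- resolve_params(grid, spec, is_pun[i])
    wp <- weight_prob(offers$p[i], par$gamma)
    u_g <- wp * value_fn(offers$O1[i], par$alpha) +
      (1 - wp) * value_fn(offers$O2[i], par$alpha)
    u_c <- value_fn(offers$Oc[i], par$alpha)
    f <- stats::plogis(par$mu * (u_g - u_c))
    if (!is.null(par$delta)) f <- clamp01(f + par$delta)
    fe <- pmin(pmax(f, eps), 1 - eps)
    ll <- ll + offers$y[i] * log(fe) + (1 - offers$y[i]) * log(1 - fe)
  }
  i_best <- which.max(ll)
  list(theta = stats::setNames(as.numeric(grid[i_best, ]), spec$par_names),
       log_likelihood = unname(ll[i_best]), n_grid = n_grid)
}

#' Fit a set of models to every participant in a cohort
#'
#' @param trials Trial table for the whole cohort.
#' @param success_table Success table for offer resolution.
#' @param specs List of `model_spec`s (default: the full 24-model family).
#' @param n_restarts Restarts per fit.
#' @param seed Master seed; per-participant streams are derived from it.
#' @return A data frame with one row per (participant, model): parameter
#'   columns (NA where a model lacks the parameter), `logL`, `k`, `n`, `aic`,
#'   `bic`, `pseudo_r2`, `converged`.
#' @export
fit_cohort <- function(trials, success_table, specs = enumerate_models(),
                       n_restarts = 20L, seed = 1L) {
  all_pars <- c("alpha", "alpha_plus", "alpha_minus", "mu", "mu_plus",
                "mu_minus", "delta", "delta_plus", "delta_minus", "gamma")
  ids <- unique(trials$participant_id)
  rows <- vector("list", length(ids) * length(specs))
  j <- 0L
  for (pid in ids) {
    tr <- trials[trials$participant_id == pid, , drop = FALSE]
    offers <- prepare_offers(tr, success_table)
    for (spec in specs) {
      fit <- fit_mle(offers, spec, NULL, n_restarts = n_restarts, seed = seed)
      pars <- stats::setNames(rep(NA_real_, length(all_pars)), all_pars)
      pars[names(fit$theta_hat)] <- fit$theta_hat
      j <- j + 1L
      rows[[j]] <- data.frame(
        participant_id = pid, code = spec$code, t(pars),
        logL = fit$log_likelihood, k = spec$k, n = fit$n_trials,
        aic = fit$aic, bic = fit$bic, pseudo_r2 = fit$pseudo_r2,
        converged = fit$converged, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
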