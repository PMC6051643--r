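## The decision models: prospect-theory value function, probability weighting,
## softmax choice rule, Pavlovian approach-avoidance offset, and the 24-member
## model family obtained by crossing joint/separate reward-punishment
## parameters with linear/weighted probability.

#' Prospect-theory value function
#'
#' Two-part power function `v(O) = O^alpha` for gains and
#' `v(O) = -lambda * (-O)^alpha` for losses, with `v(0) = 0`. `alpha < 1`
#' encodes diminishing sensitivity (risk aversion for gains, risk seeking for
#' losses); `lambda` is the loss-aversion coefficient, fixed at 1 throughout
#' this task because no gamble mixes gains and losses.
#'
#' @param O Objective outcome in points (vectorised).
#' @param alpha Risk-preference exponent in \[0, 1\] (scalar or per-outcome).
#' @param lambda Loss-aversion coefficient (> 0).
#' @return Subjective value(s).
#' @export
value_fn <- function(O, alpha, lambda = 1) {
  stopifnot(all(alpha >= 0 & alpha <= 1), lambda > 0)
  out <- ifelse(O >= 0, O^alpha, -lambda * (-O)^alpha)
  out[O == 0] <- 0  # guards 0^0 == 1 at alpha = 0
  out
}

#' One-parameter probability weighting function
#'
#' `w(p) = exp(-(-ln p)^gamma)`; `gamma = 1` is the identity (linear
#' weighting), and `w(0) = 0`, `w(1) = 1` by continuity. With `gamma = NULL`
#' the objective probability is returned unchanged.
#'
#' @param p Probability in \[0, 1\] (vectorised).
#' @param gamma Positive weighting exponent, or `NULL` for linear weighting.
#' @return Weighted probability.
#' @export
weight_prob <- function(p, gamma = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(gamma) || (length(gamma) == 1L && is.na(gamma))) return(p)
  stopifnot(all(gamma > 0))
  w <- exp(-(-log(p))^gamma)
  w[p == 0] <- 0
  w
}

#' Construct a model specification
#'
#' A model variant is defined by whether the risk preference `alpha` and
#' inverse temperature `mu` are shared across reward and punishment domains or
#' split, whether a Pavlovian offset `delta` is absent, joint, or split by
#' domain, and whether probabilities enter linearly or through the weighting
#' function (one extra parameter `gamma`).
#'
#' @param alpha_split,mu_split Logical; separate reward/punishment parameters?
#' @param delta_mode `"none"`, `"joint"` or `"split"`.
#' @param weighting `"linear"` or `"weighted"`.
#' @return A list of class `model_spec` with the flags, the free-parameter
#'   names `par_names`, the parameter count `k`, and a short `code` of the
#'   form `a{0,1}m{0,1}d{0,1,2}w{0,1}`.
#' @export
model_spec <- function(alpha_split = FALSE, mu_split = FALSE,
                       delta_mode = c("none", "joint", "split"),
                       weighting = c("linear", "weighted")) {
  delta_mode <- match.arg(delta_mode)
  weighting <- match.arg(weighting)
  par_names <- c(
    if (alpha_split) c("alpha_plus", "alpha_minus") else "alpha",
    if (mu_split) c("mu_plus", "mu_minus") else "mu",
    switch(delta_mode, none = character(0), joint = "delta",
           split = c("delta_plus", "delta_minus")),
    if (weighting == "weighted") "gamma"
  )
  code <- sprintf("a%dm%dd%dw%d", as.integer(alpha_split),
                  as.integer(mu_split),
                  match(delta_mode, c("none", "joint", "split")) - 1L,
                  as.integer(weighting == "weighted"))
  structure(
    list(alpha_split = alpha_split, mu_split = mu_split,
         delta_mode = delta_mode, weighting = weighting,
         par_names = par_names, k = length(par_names), code = code),
    class = "model_spec"
  )
}

#' Parse a model-spec code back into a specification
#'
#' @param code A code such as `"a0m0d2w0"` (the winning approach-avoidance
#'   model: joint alpha, joint mu, split delta, linear weighting).
#' @return A `model_spec`.
#' @export
parse_spec_code <- function(code) {
  m <- regmatches(code, regexec("^a([01])m([01])d([012])w([01])$", code))[[1]]
  if (length(m) != 5L) stop("malformed model spec code: ", code)
  model_spec(
    alpha_split = m[2] == "1", mu_split = m[3] == "1",
    delta_mode = c("none", "joint", "split")[as.integer(m[4]) + 1L],
    weighting = if (m[5] == "1") "weighted" else "linear"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec", x$code, "(k =", x$k, "):",
      paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the full 24-model family
#'
#' The cross of joint/split `alpha`, joint/split `mu`, `delta` absent /
#' joint / split, and linear/weighted probability. Ordering is stable:
#' prospect-theory (no delta) linear models first (IDs 1-4), then weighted PT
#' (5-8), then approach-avoidance linear (9-16) and weighted (17-24); within a
#' block models are ordered by alpha split, mu split, then joint-before-split
#' delta. The prospect-theory winner `[alpha+, alpha-, mu+, mu-]` is ID 4 and
#' the approach-avoidance winner `[alpha, mu, delta+, delta-]` is ID 10.
#'
#' @return A list of 24 `model_spec` objects, named by code.
#' @export
enumerate_models <- function() {
  specs <- list()
  for (has_delta in c(FALSE, TRUE)) {
    for (w in c("linear", "weighted")) {
      for (a in c(FALSE, TRUE)) {
        for (m in c(FALSE, TRUE)) {
          dmodes <- if (has_delta) c("joint", "split") else "none"
          for (d in dmodes) {
            specs[[length(specs) + 1L]] <- model_spec(a, m, d, w)
          }
        }
      }
    }
  }
  names(specs) <- vapply(specs, `[[`, character(1), "code")
  specs
}

## Resolve per-trial parameter values from a named theta vector, honouring
## domain splits (reward -> "_plus", punishment -> "_minus").
resolve_params <- function(theta, spec, is_punishment) {
  pick <- function(base, split) {
    if (!split) return(theta[[base]])
    plus <- theta[[paste0(base, "_plus")]]
    minus <- theta[[paste0(base, "_minus")]]
    # scalar domain + vector parameters (grid evaluation) vs per-trial domain
    if (length(is_punishment) == 1L) {
      if (is_punishment) minus else plus
    } else {
      ifelse(is_punishment, minus, plus)
    }
  }
  list(
    alpha = pick("alpha", spec$alpha_split),
    mu = pick("mu", spec$mu_split),
    delta = switch(spec$delta_mode,
                   none = NULL,
                   joint = theta[["delta"]],
                   split = pick("delta", TRUE)),
    gamma = if (spec$weighting == "weighted") theta[["gamma"]] else NULL
  )
}

check_theta <- function(theta, spec) {
  b <- par_bounds(spec)
  miss <- setdiff(spec$par_names, names(theta))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  v <- unlist(theta)[spec$par_names]
  if (any(v < b$lower - 1e-12 | v > b$upper + 1e-12)) {
    stop("parameter out of bounds for spec ", spec$code)
  }
  invisible(TRUE)
}

#' Parameter bounds for a model specification
#'
#' `alpha` in \[0, 1\]; `mu` in (0, 10\] (lower bound implemented as 1e-6);
#' `delta` in \[-1, 1\]; `gamma` in (0, 5\] when present.
#'
#' @param spec A `model_spec`.
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
par_bounds <- function(spec) {
  lo <- hi <- stats::setNames(numeric(spec$k), spec$par_names)
  for (p in spec$par_names) {
    base <- sub("_(plus|minus)$", "", p)
    r <- switch(base,
                alpha = c(0, 1),
                mu = c(1e-6, 10),
                delta = c(-1, 1),
                gamma = c(1e-6, 5))
    lo[p] <- r[1]; hi[p] <- r[2]
  }
  list(lower = lo, upper = hi)
}

#' Probability of choosing the gamble
#'
#' The utility of the gamble is `U = w(p) v(O1) + (1 - w(p)) v(O2)` (linear
#' weighting reduces to `p * v(O)` since one outcome is always 0) and of the
#' certain option `v(Oc)`. The softmax probability is
#' `F = 1 / (1 + exp(-mu (U_gamble - U_certain)))`; for approach-avoidance
#' models the Pavlovian offset `delta` is then added and the result clamped
#' into \[0, 1\] — the offset itself is never clamped.
#'
#' @param offers Data frame with columns `p`, `O1`, `O2`, `Oc`, `domain`
#'   (`"reward"` / `"punishment"`).
#' @param theta Named list/vector of parameter values satisfying `spec`.
#' @param spec A `model_spec`; on reward trials the `_plus` member of a split
#'   parameter applies, on punishment trials the `_minus` member.
#' @param check Validate `theta` against bounds (default `TRUE`).
#' @return Numeric vector of gamble probabilities, one per offer.
#' @export
gamble_prob <- function(offers, theta, spec, check = TRUE) {
  if (check) check_theta(theta, spec)
  is_pun <- offers$domain == "punishment"
  par <- resolve_params(theta, spec, is_pun)
  wp <- weight_prob(offers$p, par$gamma)
  u_g <- wp * value_fn(offers$O1, par$alpha) +
    (1 - wp) * value_fn(offers$O2, par$alpha)
  u_c <- value_fn(offers$Oc, par$alpha)
  f <- stats::plogis(par$mu * (u_g - u_c))
  if (!is.null(par$delta)) f <- clamp01(f + par$delta)
  unname(f)
}

#' Simulate gamble/skip choices from a model
#'
#' @inheritParams gamble_prob
#' @param seed Integer seed.
#' @return Integer vector of choices (1 = gamble, 0 = skip).
#' @export
simulate_choices <- function(offers, theta, spec, seed) {
  f <- gamble_prob(offers, theta, spec)
  with_seed(seed, stats::rbinom(length(f), 1L, f))
}
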