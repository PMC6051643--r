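#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a key
#'
#' Mixes an integer master seed with a character key (e.g. a participant id or
#' stage name) so that independent units of work get distinct, stable RNG
#' streams. Result is always in [0, 2^31 - 2].
#'
#' @param seed Integer master seed.
#' @param key Atomic value coerced to character.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(seed) + h) %% 2147483647)
}

## Evaluate `expr` with a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Truncated-normal draws by inverse-CDF; used for per-participant parameter
## heterogeneity (truncation at model bounds).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
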