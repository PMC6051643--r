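## Synthetic cohorts with the statistical structure of the app-based motor
## gambling study: a success-probability surface over (age group, screen bin,
## target level), age-graded approach-avoidance parameter profiles, and
## trial-by-trial choice/outcome simulation.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the study's structure: six age groups (18-24, 25-29,
#' 30-39, 40-49, 50-59, 60+), 42 trials per participant, a success surface
#' declining with target level and age and improving with screen size, and
#' approach-avoidance parameter profiles whose group medians interpolate
#' linearly between a young and an old anchor — the reward Pavlovian offset
#' `delta+` declining most steeply with age, `delta-` mildly declining
#' (more negative), `alpha` mildly declining, and `mu` flat.
#'
#' @param n_per_age_group Participants per age group (length 6, recycled).
#' @param alpha_anchors,mu_anchors,delta_plus_anchors,delta_minus_anchors
#'   Length-2 vectors `c(young, old)` of group medians for the generating
#'   model's parameters; group medians interpolate linearly across the six
#'   groups.
#' @param alpha_sd,mu_sd,delta_sd Between-participant spreads (truncated
#'   normal around the group median, truncation at model bounds).
#' @param base_rate Success probability at target level 1 for the youngest
#'   group on the smallest screen bin.
#' @param level_slope Logit decline per target level (>= 0).
#' @param screen_strength Logit gain per screen-bin step (>= 0); 0 removes the
#'   screen effect.
#' @param age_strength Logit decline per age-group step (>= 0); 0 removes the
#'   age effect.
#' @param age_level_interaction Extra logit decline per (age step x level
#'   step), scaled by level progression; steepens the level decline for older
#'   groups.
#' @param screen_mean,screen_sd Screen-size distribution (inches), truncated
#'   to \[3.5, 11\].
#' @param estimate_noise_sd Miscalibration noise (percentage points) for the
#'   probability-estimation control study.
#' @param generating_code Spec code of the generating model (default the
#'   winning approach-avoidance model).
#' @param seed Master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_age_group = rep(100L, 6L),
                          alpha_anchors = c(0.85, 0.70),
                          mu_anchors = c(0.50, 0.50),
                          delta_plus_anchors = c(0.35, 0.05),
                          delta_minus_anchors = c(-0.10, -0.25),
                          alpha_sd = 0.08, mu_sd = 0.15, delta_sd = 0.08,
                          base_rate = 0.93, level_slope = 0.55,
                          screen_strength = 0.25, age_strength = 0.25,
                          age_level_interaction = 0.06,
                          screen_mean = 5.5, screen_sd = 1.5,
                          estimate_noise_sd = 10,
                          generating_code = "a0m0d2w0",
                          seed = 1L) {
  cfg <- list(
    n_per_age_group = rep_len(as.integer(n_per_age_group), 6L),
    alpha_anchors = alpha_anchors, mu_anchors = mu_anchors,
    delta_plus_anchors = delta_plus_anchors,
    delta_minus_anchors = delta_minus_anchors,
    alpha_sd = alpha_sd, mu_sd = mu_sd, delta_sd = delta_sd,
    base_rate = base_rate, level_slope = level_slope,
    screen_strength = screen_strength, age_strength = age_strength,
    age_level_interaction = age_level_interaction,
    screen_mean = screen_mean, screen_sd = screen_sd,
    estimate_noise_sd = estimate_noise_sd,
    generating_code = generating_code,
    seed = as.integer(seed)
  )
  stopifnot(all(cfg$n_per_age_group >= 0L), cfg$level_slope >= 0,
            cfg$screen_strength >= 0, cfg$age_strength >= 0,
            cfg$base_rate > 0, cfg$base_rate < 1)
  class(cfg) <- "cohort_config"
  cfg
}

## Group medians for each generating parameter: linear interpolation between
## the young (group 1) and old (group 6) anchors.
profile_medians <- function(anchors) {
  anchors[1] + (anchors[2] - anchors[1]) * (0:5) / 5
}

#' True success-probability surface of a synthetic cohort
#'
#' A logistic surface over 6 age groups x 4 screen bins x 7 target levels:
#' monotone non-increasing in target level, non-decreasing in screen bin, and
#' non-increasing in age, with an optional age-by-level interaction. Rates are
#' clipped to \[0.02, 0.98\].
#'
#' @param config A [cohort_config()].
#' @return A `success_table` (group mode) with 168 rows and `n = NA`.
#' @export
sample_success_surface <- function(config) {
  grid <- expand.grid(age_group = 1:6, screen_bin = c(4L, 6L, 8L, 10L),
                      target_level = 1:7)
  bin_idx <- match(grid$screen_bin, c(4L, 6L, 8L, 10L))
  lg <- stats::qlogis(config$base_rate) -
    config$level_slope * (grid$target_level - 1) +
    config$screen_strength * (bin_idx - 1) -
    config$age_strength * (grid$age_group - 1) -
    config$age_level_interaction * (grid$age_group - 1) *
      (grid$target_level - 1) / 6
  grid$rate <- pmin(pmax(stats::plogis(lg), 0.02), 0.98)
  grid$n <- NA_integer_
  attr(grid, "mode") <- "group"
  class(grid) <- c("success_table", class(grid))
  grid
}

#' Generate a synthetic cohort of motor-gambling sessions
#'
#' Per participant: draws an age group (per the configured counts), screen
#' size, and true model parameters (truncated-normal around the age-graded
#' group medians); builds a seeded 42-trial schedule; computes the gamble
#' probability on each trial from the generating model and the true success
#' surface; draws the choice, and — on gambled trials only — the motor
#' outcome and resulting points. Skipped trials never carry a motor outcome.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `trials` (trial-by-trial
#'   table in the standard CSV schema), `participants` (demographics plus the
#'   true generating parameters), `surface` (the true success table), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  spec <- parse_spec_code(config$generating_code)
  surface <- sample_success_surface(config)
  med <- list(
    alpha = profile_medians(config$alpha_anchors),
    mu = profile_medians(config$mu_anchors),
    delta_plus = profile_medians(config$delta_plus_anchors),
    delta_minus = profile_medians(config$delta_minus_anchors)
  )
  n_total <- sum(config$n_per_age_group)
  age_group <- rep(1:6, times = config$n_per_age_group)
  participants <- with_seed(derive_seed(config$seed, "participants"), {
    data.frame(
      participant_id = sprintf("P%04d", seq_len(n_total)),
      age_group = age_group,
      gender = sample(c("female", "male"), n_total, replace = TRUE),
      education = sample(c("school", "university", "advanced"), n_total,
                         replace = TRUE),
      screen_inches = round(rtruncnorm(n_total, config$screen_mean,
                                       config$screen_sd, 3.5, 11), 1),
      alpha = rtruncnorm(n_total, med$alpha[age_group], config$alpha_sd, 0, 1),
      mu = rtruncnorm(n_total, med$mu[age_group], config$mu_sd, 1e-6, 10),
      delta_plus = rtruncnorm(n_total, med$delta_plus[age_group],
                              config$delta_sd, -1, 1),
      delta_minus = rtruncnorm(n_total, med$delta_minus[age_group],
                               config$delta_sd, -1, 1),
      stringsAsFactors = FALSE
    )
  })
  trial_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    prt <- participants[i, ]
    sched <- build_schedule(derive_seed(config$seed, paste0("sched-", prt$participant_id)))
    tr <- data.frame(
      participant_id = prt$participant_id, age_group = prt$age_group,
      gender = prt$gender, education = prt$education,
      screen_inches = prt$screen_inches,
      sched, stringsAsFactors = FALSE
    )
    p <- lookup_success(surface, tr)
    offers <- data.frame(p = p, O1 = tr$success_value, O2 = tr$fail_value,
                         Oc = tr$certain_value, domain = tr$domain)
    theta <- c(alpha = prt$alpha, mu = prt$mu,
               delta_plus = prt$delta_plus, delta_minus = prt$delta_minus)
    theta <- theta[spec$par_names]
    f <- gamble_prob(offers, theta, spec)
    sim <- with_seed(derive_seed(config$seed, paste0("play-", prt$participant_id)), {
      choice <- stats::rbinom(nrow(tr), 1L, f)
      succ <- ifelse(choice == 1L, stats::rbinom(nrow(tr), 1L, p), NA_integer_)
      list(choice = choice, succ = succ)
    })
    tr$choice <- sim$choice
    tr$motor_success <- sim$succ
    tr$points_delta <- ifelse(
      tr$choice == 0L, tr$certain_value,
      ifelse(sim$succ == 1L, tr$success_value, tr$fail_value)
    )
    tr$trajectory_angle <- NULL
    trial_rows[[i]] <- tr
  }
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  trials <- trials[, c("participant_id", "age_group", "gender", "education",
                       "screen_inches", "block", "target_level", "domain",
                       "certain_value", "success_value", "fail_value",
                       "choice", "motor_success", "points_delta")]
  structure(list(trials = trials, participants = participants,
                 surface = surface, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$participants), "participants,",
      nrow(x$trials), "trials (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Generate the probability-estimation control study
#'
#' Each participant performs 42 tapping trials; before each, they state a
#' verbal estimate of their success probability on the 0-100% scale in steps
#' of 10. Estimates are the true surface probability plus configurable
#' miscalibration (a constant bias and/or noise), rounded to the grid and
#' clipped; the motor outcome is Bernoulli in the true probability.
#'
#' @param config A [cohort_config()] (supplies the surface, screen
#'   distribution and `estimate_noise_sd`).
#' @param n_per_group Participants per age group (study control used 20).
#' @param bias Constant miscalibration in percentage points (default 0).
#' @param seed Seed (defaults to the config's).
#' @return Data frame with one row per estimation trial: `participant_id`,
#'   `age_group`, `screen_inches`, `target_level`, `p_true`, `estimate`,
#'   `motor_success`.
#' @export
generate_estimation_study <- function(config, n_per_group = 20L, bias = 0,
                                      seed = NULL) {
  stopifnot(n_per_group >= 1L)
  seed <- seed %||% config$seed
  surface <- sample_success_surface(config)
  n_total <- 6L * n_per_group
  rows <- with_seed(derive_seed(seed, "estimation"), {
    out <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      ag <- ((i - 1L) %/% n_per_group) + 1L
      scr <- round(rtruncnorm(1L, config$screen_mean, config$screen_sd,
                              3.5, 11), 1)
      lvl <- rep(1:7, times = 6)[sample.int(42L)]
      qr <- data.frame(age_group = ag, screen_inches = scr, target_level = lvl)
      p <- lookup_success(surface, qr)
      est <- p * 100 + bias +
        stats::rnorm(42L, 0, config$estimate_noise_sd)
      est <- pmin(pmax(round(est / 10) * 10, 0), 100)
      out[[i]] <- data.frame(
        participant_id = sprintf("E%03d", i), age_group = ag,
        screen_inches = scr, target_level = lvl, p_true = p,
        estimate = est,
        motor_success = stats::rbinom(42L, 1L, p),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  rows
}
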