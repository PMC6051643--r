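# Shared fixtures: all synthetic, built in code at test time.

aa_spec <- parse_spec_code("a0m0d2w0")
pt_spec <- parse_spec_code("a0m0d0w0")

# Offer table for a single simulated participant: `n_schedules` concatenated
# 42-trial schedules resolved against the true success surface.
make_template_offers <- function(n_schedules = 1L, age_group = 3L,
                                 screen_inches = 5.5, seed = 100L,
                                 config = cohort_config()) {
  surf <- sample_success_surface(config)
  sched <- do.call(rbind, lapply(seq_len(n_schedules), function(i) {
    build_schedule(derive_seed(seed, i))
  }))
  sched$age_group <- age_group
  sched$screen_inches <- screen_inches
  sched$participant_id <- "sim"
  prepare_offers(sched, surf)
}

# Small cohort for integration-style tests.
make_small_cohort <- function(n_per_group = 5L, seed = 42L, ...) {
  generate_cohort(cohort_config(n_per_age_group = rep(n_per_group, 6L),
                                seed = seed, ...))
}

# Hand-built trial rows for one participant with fully controlled payoffs.
make_manual_trials <- function(pid = "M1", choice, motor_success,
                               target_level = 1L, domain = "reward",
                               age_group = 1L, screen_inches = 4) {
  n <- length(choice)
  data.frame(
    participant_id = pid, age_group = age_group, gender = "female",
    education = "school", screen_inches = screen_inches, block = 1L,
    target_level = target_level, domain = domain,
    certain_value = if (domain == "reward") 10 else -10,
    success_value = if (domain == "reward") 20 else 0,
    fail_value = if (domain == "reward") 0 else -20,
    choice = choice, motor_success = motor_success,
    points_delta = 0, stringsAsFactors = FALSE
  )
}
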