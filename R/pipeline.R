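## Orchestration: generate -> fit -> select -> recover -> stats as a
## resumable, seeded pipeline over flat CSV/JSON artefacts, plus validation of
## trial tables.

#' Read a cohort configuration from YAML or JSON
#'
#' Any keys absent from the file fall back to the [cohort_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(cohort_config, raw)
}

pipeline_paths <- function(output_dir) {
  list(
    trials = file.path(output_dir, "cohort_trials.csv"),
    truth = file.path(output_dir, "cohort_truth.csv"),
    surface = file.path(output_dir, "success_surface.csv"),
    success = file.path(output_dir, "success_table.csv"),
    fits = file.path(output_dir, "fits.csv"),
    summed = file.path(output_dir, "model_comparison.csv"),
    winners = file.path(output_dir, "model_winners.csv"),
    selection = file.path(output_dir, "model_selection.json"),
    recovery = file.path(output_dir, "parameter_recovery.csv"),
    stats = file.path(output_dir, "behaviour_stats.csv"),
    curves = file.path(output_dir, "gamble_rate_curves.csv"),
    manifest = file.path(output_dir, "manifest.json")
  )
}

#' Run the analysis pipeline
#'
#' Stages, in dependency order: `generate` (synthetic cohort + true surface),
#' `fit` (all requested models to every participant, using the group success
#' table estimated from the generated data), `select` (model comparison),
#' `recover` (parameter recovery for typical parameter sets), `stats`
#' (optimality discrepancy, binned curves, partial Spearman of fitted
#' `delta_plus` against age). Later stages read the CSV artefacts of earlier
#' ones, so a stage subset can resume a previous run.
#'
#' @param config A `cohort_config`, or a path to a YAML/JSON config file.
#' @param output_dir Directory for artefacts (created if needed).
#' @param stages Character subset of
#'   `c("generate", "fit", "select", "recover", "stats")`.
#' @param models Spec codes to fit (default: the winning approach-avoidance
#'   and prospect-theory models plus their joint-delta neighbours); `"all"`
#'   fits the full 24-model family.
#' @param n_restarts Restarts per fit.
#' @param n_recovery_sims Simulations per recovery parameter set.
#' @param seed Optional master-seed override of the config's seed.
#' @return The run manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, output_dir,
                         stages = c("generate", "fit", "select", "recover",
                                    "stats"),
                         models = c("a0m0d2w0", "a0m0d1w0", "a1m1d0w0",
                                    "a0m0d0w0"),
                         n_restarts = 10L, n_recovery_sims = 10L,
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(output_dir)
  if (identical(models, "all")) models <- names(enumerate_models())
  specs <- lapply(models, parse_spec_code)
  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("motorgamble")),
                   stages = stages, models = models, artefacts = list(),
                   counts = list(), timing_s = list())
  note <- function(stage, name, path, n) {
    manifest$artefacts[[name]] <<- path
    manifest$counts[[name]] <<- n
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    manifest$timing_s[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires missing artefact: ", path,
           " (run the upstream stage first)")
    }
    path
  }

  if ("generate" %in% stages) timed("generate", {
    cohort <- generate_cohort(config)
    write_trials(cohort$trials, paths$trials)
    utils::write.csv(cohort$participants, paths$truth, row.names = FALSE)
    write_success_table(cohort$surface, paths$surface)
    note("generate", "trials", paths$trials, nrow(cohort$trials))
    note("generate", "truth", paths$truth, nrow(cohort$participants))
    note("generate", "surface", paths$surface, nrow(cohort$surface))
  })

  if ("fit" %in% stages) timed("fit", {
    trials <- read_trials(need(paths$trials, "fit"))
    st <- estimate_success_table(trials, "group")
    write_success_table(st, paths$success)
    fits <- fit_cohort(trials, st, specs = specs, n_restarts = n_restarts,
                       seed = config$seed)
    utils::write.csv(fits, paths$fits, row.names = FALSE, na = "")
    note("fit", "success_table", paths$success, nrow(st))
    note("fit", "fits", paths$fits, nrow(fits))
  })

  if ("select" %in% stages) timed("select", {
    fits <- utils::read.csv(need(paths$fits, "select"))
    rep <- compare_models(fits)
    utils::write.csv(rep$summed, paths$summed, row.names = FALSE)
    utils::write.csv(rep$winners, paths$winners, row.names = FALSE)
    jsonlite::write_json(
      list(winner_bic = rep$winner_bic, winner_aic = rep$winner_aic),
      paths$selection, auto_unbox = TRUE
    )
    note("select", "summed_criteria", paths$summed, nrow(rep$summed))
    note("select", "winner_matrix", paths$winners, nrow(rep$winners))
    note("select", "selection", paths$selection, 1L)
  })

  if ("recover" %in% stages) timed("recover", {
    trials <- read_trials(need(paths$trials, "recover"))
    st <- estimate_success_table(trials, "group")
    tmpl <- prepare_offers(trials[trials$participant_id ==
                                    trials$participant_id[1], ], st)
    rec <- parameter_recovery(typical_parameter_sets(), parse_spec_code("a0m0d2w0"),
                              n_sims = n_recovery_sims, template_offers = tmpl,
                              n_restarts = n_restarts, seed = config$seed)
    utils::write.csv(rec$summary, paths$recovery, row.names = FALSE)
    note("recover", "recovery", paths$recovery, nrow(rec$summary))
  })

  if ("stats" %in% stages) timed("stats", {
    trials <- read_trials(need(paths$trials, "stats"))
    st <- estimate_success_table(trials, "group")
    curves <- binned_gamble_rate(trials, st, seed = config$seed)
    utils::write.csv(curves, paths$curves, row.names = FALSE)
    ids <- unique(trials$participant_id)
    disc <- t(vapply(ids, function(pid) {
      optimality_discrepancy(trials[trials$participant_id == pid, ], st)
    }, numeric(2)))
    pstats <- data.frame(participant_id = ids,
                         discrepancy_reward = disc[, 1],
                         discrepancy_punishment = disc[, 2])
    if (file.exists(paths$fits)) {
      fits <- utils::read.csv(need(paths$fits, "stats"))
      aa <- fits[fits$code == "a0m0d2w0", ]
      pstats <- merge(pstats, aa[, c("participant_id", "delta_plus",
                                     "delta_minus", "alpha", "mu")],
                      by = "participant_id", all.x = TRUE)
    }
    demo <- unique(trials[, c("participant_id", "age_group", "gender",
                              "education")])
    pstats <- merge(pstats, demo, by = "participant_id")
    utils::write.csv(pstats, paths$stats, row.names = FALSE, na = "")
    note("stats", "curves", paths$curves, nrow(curves))
    note("stats", "participant_stats", paths$stats, nrow(pstats))
  })

  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Typical-participant parameter sets used for recovery diagnostics
#'
#' Three sets spanning the plausible region of the winning approach-avoidance
#' model: moderate, shallow-utility/low-temperature, and
#' high-alpha/strong-avoidance profiles.
#'
#' @return Named list of named parameter vectors.
#' @export
typical_parameter_sets <- function() {
  list(
    moderate = c(alpha = 0.8, mu = 0.3, delta_plus = 0.2, delta_minus = -0.2),
    shallow = c(alpha = 0.7, mu = 0.15, delta_plus = 0.35, delta_minus = -0.05),
    steep = c(alpha = 0.9, mu = 0.5, delta_plus = 0.1, delta_minus = -0.3)
  )
}

#' Validate a trial-by-trial table
#'
#' Checks the schema (required columns), per-participant completeness (42
#' trials, each value combination once per target level), domain/payoff
#' consistency, and value bounds. Malformed rows are enumerated in the report,
#' never dropped.
#'
#' @param trials A trial table or a CSV path.
#' @return A list of class `validation_report`: `n_trials`,
#'   `n_participants`, `violations` (data frame with `rule`,
#'   `participant_id`, `detail`), and `ok` (no violations).
#' @export
validate_trials <- function(trials) {
  if (is.character(trials)) trials <- read_trials(trials)
  req <- c("participant_id", "age_group", "gender", "education",
           "screen_inches", "block", "target_level", "domain",
           "certain_value", "success_value", "fail_value", "choice",
           "motor_success", "points_delta")
  v <- list()
  flag <- function(rule, pid, detail) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, participant_id = pid,
                                       detail = detail, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols)) {
    flag("schema", NA_character_,
         paste("missing columns:", paste(missing_cols, collapse = ", ")))
    return(structure(list(n_trials = nrow(trials), n_participants = NA_integer_,
                          violations = do.call(rbind, v), ok = FALSE),
                     class = "validation_report"))
  }
  bad_choice <- !trials$choice %in% c(0L, 1L)
  for (i in which(bad_choice)) {
    flag("choice_domain", trials$participant_id[i],
         paste("choice =", trials$choice[i]))
  }
  bad_level <- !trials$target_level %in% 1:7
  for (i in which(bad_level)) {
    flag("target_level", trials$participant_id[i],
         paste("target_level =", trials$target_level[i]))
  }
  rw <- trials$domain == "reward" &
    (trials$certain_value != 10 | trials$fail_value != 0 |
       !trials$success_value %in% c(20, 60, 100))
  pn <- trials$domain == "punishment" &
    (trials$certain_value != -10 | trials$success_value != 0 |
       !trials$fail_value %in% c(-20, -60, -100))
  for (i in which(rw | pn)) {
    flag("payoff_structure", trials$participant_id[i],
         paste("domain =", trials$domain[i]))
  }
  skip_succ <- trials$choice == 0L & !is.na(trials$motor_success)
  for (i in which(skip_succ)) {
    flag("skip_has_outcome", trials$participant_id[i], "motor_success on skipped trial")
  }
  for (pid in unique(trials$participant_id)) {
    tr <- trials[trials$participant_id == pid, ]
    if (nrow(tr) != 42L) {
      flag("completeness", pid, paste(nrow(tr), "trials (expected 42)"))
      next
    }
    combo_per_level <- stats::aggregate(
      rep(1L, nrow(tr)),
      by = list(domain = tr$domain, sv = tr$success_value,
                fv = tr$fail_value, lvl = tr$target_level), FUN = sum)
    if (nrow(combo_per_level) != 42L || any(combo_per_level$x != 1L)) {
      flag("value_combinations", pid,
           "each of the 6 value combinations must appear once per target level")
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(0), participant_id = character(0),
               detail = character(0))
  structure(list(n_trials = nrow(trials),
                 n_participants = length(unique(trials$participant_id)),
                 violations = violations, ok = nrow(violations) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", x$n_trials, "trials,", x$n_participants, "participants,",
      nrow(x$violations), "violation(s)\n")
  if (nrow(x$violations)) print(utils::head(x$violations, 10), row.names = FALSE)
  invisible(x)
}
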