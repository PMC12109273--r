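# Readers/writers for trial and results tables, run configuration, and the
# end-to-end pipeline.

.trial_columns <- c("participant", "configuration", "stimulus", "trial", "t",
                    "target_x", "target_y", "pert_x", "pert_y",
                    "cursor_x", "cursor_y")

#' Write / read trial records as a long-format delimited table
#'
#' One row per time sample, columns `participant`, `configuration`,
#' `stimulus`, `trial`, `t`, `target_x`, `target_y`, `pert_x`, `pert_y`,
#' `cursor_x`, `cursor_y`. Values are serialised at full double precision so
#' a write/read round-trip reproduces the numeric content exactly. On
#' reading, the sample rate is inferred from the time column and validated
#' constant within each trial.
#'
#' @param trials list of `trial_record`s.
#' @param path CSV file path.
#' @return `read_trials()` returns a list of `trial_record`s.
#' @export
write_trials <- function(trials, path) {
  stopifnot(length(trials) >= 1)
  rows <- lapply(trials, function(tr) {
    n <- length(tr$cursor$x)
    tibble::tibble(
      participant = tr$participant_id,
      configuration = tr$configuration,
      stimulus = tr$stimulus_label,
      trial = tr$trial,
      t = (seq_len(n) - 1) / tr$cursor$sample_rate,
      target_x = tr$target$x, target_y = tr$target$y,
      pert_x = tr$perturbation$x, pert_y = tr$perturbation$y,
      cursor_x = tr$cursor$x, cursor_y = tr$cursor$y
    )
  })
  df <- dplyr::bind_rows(rows)
  # 17 significant digits + base parser: doubles round-trip bit-exactly
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(df))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(
    df,
    interaction(df$participant, df$configuration, df$stimulus, df$trial,
                drop = TRUE, lex.order = TRUE)
  )
  lapply(unname(groups), function(g) {
    dt <- diff(g$t)
    if (any(dt <= 0)) {
      stop(sprintf("non-monotone time within trial (%s, %s, %s)",
                   g$participant[1], g$configuration[1], g$stimulus[1]),
           call. = FALSE)
    }
    if (max(dt) - min(dt) > 1e-6) {
      stop(sprintf("irregular sampling within trial (%s, %s, %s)",
                   g$participant[1], g$configuration[1], g$stimulus[1]),
           call. = FALSE)
    }
    fs <- 1 / stats::median(dt)
    traj <- function(x, y) structure(list(x = x, y = y, sample_rate = fs),
                                     class = "trajectory")
    new_trial_record(
      g$participant[1], g$configuration[1], g$stimulus[1],
      target = traj(g$target_x, g$target_y),
      perturbation = traj(g$pert_x, g$pert_y),
      cursor = traj(g$cursor_x, g$cursor_y),
      trial = g$trial[1]
    )
  })
}

#' Write a cohort with its ground-truth sidecar
#'
#' Writes the cohort's trials as one long CSV plus a JSON sidecar holding the
#' planted ground truth (participant parameters, realised effect multipliers,
#' seed).
#'
#' @param cohort a `gvs_cohort`.
#' @param trials_path CSV path.
#' @param truth_path JSON path.
#' @export
write_cohort <- function(cohort, trials_path, truth_path) {
  stopifnot(inherits(cohort, "gvs_cohort"))
  write_trials(cohort$trials, trials_path)
  jsonlite::write_json(
    list(participants = cohort$truth$participants,
         effect = cohort$truth$effect,
         seed = cohort$truth$seed,
         n_sham_trials = cohort$truth$n_sham_trials),
    truth_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(trials_path)
}

#' Run configuration
#'
#' Assembles and validates the configuration of a full pipeline run. Exactly
#' one of `simulation` (a [sim_config()]) or `input_path` (a trial CSV
#' written by [write_trials()]) must be supplied.
#'
#' @param simulation a [sim_config()], or `NULL` when reading data.
#' @param input_path path to a long-format trial CSV, or `NULL`.
#' @param regressor_set `"full"` or `"target_only"` (see [trial_errors()]).
#' @param target_y_freq target Lissajous Y frequency in Hz.
#' @param bootstrap_resamples resamples for [median_se_bootstrap()].
#' @param output_dir directory for report files, or `NULL` to skip writing.
#' @param seed integer seed (overrides the simulation block's seed so one
#'   value governs the whole run).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(), input_path = NULL,
                       regressor_set = c("full", "target_only"),
                       target_y_freq = 0.1, bootstrap_resamples = 1000,
                       output_dir = NULL, seed = 1L) {
  regressor_set <- match.arg(regressor_set)
  if (is.null(simulation) == is.null(input_path)) {
    stop("exactly one of `simulation` or `input_path` must be given",
         call. = FALSE)
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "sim_config"))
    simulation$seed <- as.integer(seed)
  } else if (!file.exists(input_path)) {
    stop("input file does not exist: ", input_path, call. = FALSE)
  }
  structure(
    list(simulation = simulation, input_path = input_path,
         regressor_set = regressor_set, target_y_freq = target_y_freq,
         bootstrap_resamples = bootstrap_resamples,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Schema: optional `simulation` block (`n_participants`,
#' `participant_heterogeneity_sd`, `n_sham_trials`, and timeline fields
#' `trial_duration`, `sample_rate`) or `input_path`; optional
#' `regressor_set`, `target_y_freq`, `bootstrap_resamples`, `output_dir`,
#' `seed`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("simulation", "input_path", "regressor_set", "target_y_freq",
             "bootstrap_resamples", "output_dir", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  simulation <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    tl_fields <- intersect(names(sim), c("trial_duration", "break_duration",
                                         "sample_rate"))
    timeline <- do.call(trial_timeline, sim[tl_fields])
    sim_fields <- intersect(names(sim), c("n_participants",
                                          "participant_heterogeneity_sd",
                                          "n_sham_trials"))
    simulation <- do.call(sim_config, c(sim[sim_fields],
                                        list(timeline = timeline)))
  }
  args <- cfg[intersect(names(cfg), setdiff(known, "simulation"))]
  do.call(run_config, c(list(simulation = simulation), args))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis: obtain trials (simulated or read from
#' disk), compute the sub-trial error table, per-condition and
#' cross-configuration mean errors, the per-participant configuration
#' error-difference table, the individualised-stimulus choices, the
#' per-stimulus improvement report, and the statistical tests (overall and
#' per-stimulus mixed-effects configuration contrasts with BH-FDR adjustment,
#' and the paired signed-rank test of sham versus individualised error). A
#' machine-readable manifest (seed, configuration hash, package version)
#' accompanies the bundle; re-running with the same configuration reproduces
#' the bundle exactly.
#'
#' @param config a [run_config()].
#' @return A list of class `gvs_report` with elements `subtrials`, `metrics`,
#'   `cross_config`, `delta_err`, `choices`, `improvement`, `stats`,
#'   `best_overall`, `manifest`, and (for simulated runs) `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    trials <- cohort$trials
    truth <- cohort$truth
  } else {
    trials <- read_trials(config$input_path)
  }

  subtrials <- subtrial_error_table(trials,
                                    regressor_set = config$regressor_set,
                                    target_y_freq = config$target_y_freq)
  metrics <- metrics_table(subtrials)
  cross <- cross_config_means(subtrials)
  has_gvs <- any(metrics$stimulus_label != "SHAM")
  both_cfg <- length(unique(metrics$configuration)) == 2

  deltas <- if (both_cfg) delta_err_table(subtrials) else NULL
  choices <- if (has_gvs) select_individualised(metrics) else NULL
  improvement <- improvement_table(subtrials)

  stats_res <- NULL
  if (both_cfg) {
    overall <- lme_config_contrast(subtrials, scope = "all")
    per_stim <- if (has_gvs) lme_config_contrast_by_stimulus(subtrials) else NULL
    stats_res <- dplyr::bind_rows(overall, per_stim)
  }
  if (has_gvs) {
    sham <- cross |>
      dplyr::filter(.data$stimulus_label == "SHAM") |>
      dplyr::arrange(.data$participant_id)
    if (nrow(sham) >= 5 && !is.null(choices)) {
      ind <- dplyr::arrange(choices, .data$participant_id)
      stats_res <- dplyr::bind_rows(
        stats_res, wilcoxon_paired(sham$mean_err, ind$mean_err)
      )
    }
  }

  gvs_rows <- improvement[improvement$stimulus_label != "SHAM", ]
  best_overall <- if (nrow(gvs_rows) > 0) {
    gvs_rows$stimulus_label[which.max(gvs_rows$improvement_over_sham_pct)]
  } else {
    NA_character_
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    package = "gvstrack",
    version = as.character(utils::packageVersion("gvstrack")),
    n_trials = length(trials)
  )

  report <- structure(
    list(subtrials = subtrials, metrics = metrics, cross_config = cross,
         delta_err = deltas, choices = choices, improvement = improvement,
         stats = stats_res, best_overall = best_overall,
         manifest = manifest, truth = truth),
    class = "gvs_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a report bundle to disk
#'
#' Writes each table of a [run_pipeline()] bundle as CSV, the improvement
#' report additionally as JSON, and the manifest as JSON. Every file name is
#' prefixed-free and the manifest carries the configuration hash that
#' reproduces the bundle.
#'
#' @param report a `gvs_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gvs_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(dir, name)
  readr::write_csv(report$subtrials, out("subtrial_errors.csv"))
  readr::write_csv(report$metrics, out("metrics.csv"))
  readr::write_csv(report$cross_config, out("cross_config_means.csv"))
  if (!is.null(report$delta_err)) {
    readr::write_csv(report$delta_err, out("delta_err.csv"))
  }
  if (!is.null(report$choices)) {
    readr::write_csv(report$choices, out("individualised_choices.csv"))
  }
  readr::write_csv(report$improvement, out("improvement.csv"))
  jsonlite::write_json(report$improvement, out("improvement.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(report$stats)) {
    readr::write_csv(report$stats, out("stats.csv"))
  }
  jsonlite::write_json(report$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.gvs_report <- function(x, ...) {
  cat(sprintf("<gvs_report> %d trials; best overall stimulus: %s\n",
              x$manifest$n_trials, x$best_overall))
  if (!is.null(x$improvement)) {
    print(x$improvement)
  }
  invisible(x)
}
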