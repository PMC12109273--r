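# Synthetic-cohort simulator: cursor trajectories with planted, stimulus- and
# configuration-dependent error magnitudes standing in for human recordings.
#
# The cursor model is
#   cursor(t) = gain * target(t - lag) + perturbation(t) + eps(t),
# where eps is zero-mean Gaussian noise low-pass filtered at the
# participant's motor-noise bandwidth, with standard deviation
# base_noise_sd * multiplier(stimulus, configuration). The stimulus waveform
# itself never enters the cursor equation: stimuli act only through the
# planted effect multipliers, because the pipeline measures effects on error
# magnitude, not a transduction model.

#' Trial record constructor
#'
#' One 45 s tracking trial: identifiers plus the aligned target,
#' perturbation, and cursor trajectories (equal length and sample rate).
#'
#' @param participant_id,configuration,stimulus_label identifiers.
#' @param target,perturbation,cursor `trajectory` objects.
#' @param trial replicate index within (participant, configuration,
#'   stimulus); > 1 only for repeated sham trials.
#' @return A list of class `trial_record`.
#' @export
new_trial_record <- function(participant_id, configuration, stimulus_label,
                             target, perturbation, cursor, trial = 1L) {
  stopifnot(
    inherits(target, "trajectory"), inherits(perturbation, "trajectory"),
    inherits(cursor, "trajectory"),
    length(target$x) == length(cursor$x),
    length(perturbation$x) == length(cursor$x),
    target$sample_rate == cursor$sample_rate
  )
  structure(
    list(participant_id = participant_id, configuration = configuration,
         stimulus_label = stimulus_label, trial = as.integer(trial),
         target = target, perturbation = perturbation, cursor = cursor),
    class = "trial_record"
  )
}

#' Participant model for the simulator
#'
#' Parameters of one synthetic participant's visuomotor response: a response
#' `gain` applied to the (lagged) target, a visuomotor `lag` in seconds, the
#' baseline motor-noise standard deviation in screen units, and the low-pass
#' bandwidth of that noise in Hz. Defaults describe a plausible tracking
#' performance: unity gain, 200 ms visuomotor delay, noise at 15% of the
#' unit target amplitude, band-limited below 2 Hz so residuals are smooth
#' and autocorrelated like real motor error.
#'
#' @param participant_id identifier string.
#' @param gain cursor response scaling (> 0).
#' @param lag visuomotor delay in seconds (>= 0).
#' @param base_noise_sd motor-noise SD in screen units (>= 0).
#' @param noise_bandwidth low-pass cut-off of the motor noise in Hz.
#' @return A list of class `participant_model`.
#' @export
participant_model <- function(participant_id, gain = 1, lag = 0.2,
                              base_noise_sd = 0.15, noise_bandwidth = 2) {
  stopifnot(gain > 0, lag >= 0, base_noise_sd >= 0, noise_bandwidth > 0)
  structure(
    list(participant_id = participant_id, gain = gain, lag = lag,
         base_noise_sd = base_noise_sd, noise_bandwidth = noise_bandwidth),
    class = "participant_model"
  )
}

#' Planted stimulus effect maps
#'
#' An effect map assigns each (stimulus label, configuration) cell a positive
#' noise multiplier; the sham multiplier (1) is the reference level, and a
#' multiplier below 1 plants a stimulus that reduces tracking error.
#'
#' `default_effect_map()` encodes the study conditions the simulator
#' emulates: GVS8 is the best overall stimulus, with a noise multiplier of
#' 0.8 relative to sham (a 25% error-rate improvement), the remaining
#' stimuli plant improvements between 4% and 23%, and the two electrode
#' configurations are equivalent on average. Multipliers are
#' `1 / (1 + PI/100)` for planted improvement percentages
#' PI = (12, 19, 13, 23, 7, 4, 21, 25) for GVS1..GVS8.
#'
#' `planted_optimum_map()` builds the simpler map used for recovery studies:
#' every cell has multiplier `contrast` except a single planted optimum cell
#' with multiplier 1 (sham stays at 1).
#'
#' @param configurations configurations to include.
#' @return A tibble with columns `stimulus_label`, `configuration`,
#'   `multiplier`.
#' @export
default_effect_map <- function(configurations = gvs_configurations()) {
  planted_pi <- c(GVS1 = 12, GVS2 = 19, GVS3 = 13, GVS4 = 23,
                  GVS5 = 7, GVS6 = 4, GVS7 = 21, GVS8 = 25)
  tidyr::expand_grid(
    stimulus_label = c(names(planted_pi), "SHAM"),
    configuration = configurations
  ) |>
    dplyr::mutate(
      multiplier = 1 / (1 + c(planted_pi, SHAM = 0)[.data$stimulus_label] / 100)
    )
}

#' @rdname default_effect_map
#' @param optimum_label,optimum_configuration the planted optimal cell.
#' @param contrast multiplier of every other non-sham cell (> 1).
#' @export
planted_optimum_map <- function(optimum_label, optimum_configuration,
                                contrast = 1.3) {
  stopifnot(contrast > 1)
  bank_labels <- c(names(.gvs_bank_freqs), "SHAM")
  stopifnot(optimum_label %in% setdiff(bank_labels, "SHAM"),
            optimum_configuration %in% gvs_configurations())
  map <- tidyr::expand_grid(
    stimulus_label = bank_labels,
    configuration = gvs_configurations()
  ) |>
    dplyr::mutate(multiplier = dplyr::if_else(.data$stimulus_label == "SHAM",
                                              1, contrast))
  map$multiplier[map$stimulus_label == optimum_label &
                   map$configuration == optimum_configuration] <- 1
  map
}

effect_multiplier <- function(effect_map, stimulus_label, configuration) {
  hit <- effect_map$stimulus_label == stimulus_label &
    effect_map$configuration == configuration
  if (sum(hit) != 1L) {
    stop(sprintf("effect map has no unique entry for (%s, %s)",
                 stimulus_label, configuration), call. = FALSE)
  }
  effect_map$multiplier[hit]
}

#' Simulation configuration
#'
#' Bundles everything needed to simulate a cohort reproducibly. Defaults
#' mirror the emulated study design: 10 participants, 45 s trials at 60 Hz,
#' two electrode configurations, the 8-stimulus GVS bank plus sham, and
#' moderate between-participant heterogeneity in stimulus response.
#'
#' @param n_participants number of participants (>= 1).
#' @param timeline a [trial_timeline()].
#' @param effect_map tibble of planted multipliers (see
#'   [default_effect_map()]); an optional `participant_id` column makes the
#'   map participant-specific.
#' @param participant_heterogeneity_sd SD (log scale) of the per-participant
#'   lognormal perturbation applied to each non-sham effect-map cell; 0
#'   disables heterogeneity so the planted map is exact for everyone.
#' @param n_sham_trials sham replicates per configuration (1 or 2).
#' @param seed integer seed governing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10,
                       timeline = trial_timeline(),
                       effect_map = default_effect_map(),
                       participant_heterogeneity_sd = 0.1,
                       n_sham_trials = 1,
                       seed = 1L) {
  stopifnot(n_participants >= 1, inherits(timeline, "trial_timeline"),
            participant_heterogeneity_sd >= 0, n_sham_trials %in% c(1L, 2L),
            all(effect_map$multiplier > 0))
  structure(
    list(n_participants = as.integer(n_participants), timeline = timeline,
         effect_map = effect_map,
         participant_heterogeneity_sd = participant_heterogeneity_sd,
         n_sham_trials = as.integer(n_sham_trials), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# zero-mean Gaussian noise low-pass filtered by a first-order recursion at
# cut-off `bandwidth`, rescaled to exact stationary SD `sd`
lowpass_noise <- function(n, sd, bandwidth, sample_rate) {
  if (sd == 0) return(numeric(n))
  alpha <- exp(-2 * pi * bandwidth / sample_rate)
  white <- stats::rnorm(n)
  y <- stats::filter((1 - alpha) * white, alpha, method = "recursive")
  stationary_sd <- (1 - alpha) / sqrt(1 - alpha^2)
  as.numeric(y) * sd / stationary_sd
}

shift_with_edge_hold <- function(x, k) {
  if (k <= 0) return(x)
  n <- length(x)
  c(rep(x[1], min(k, n)), x[seq_len(max(0, n - k))])
}

#' Simulate one tracking trial
#'
#' Generates the cursor path of one synthetic trial under the cursor model
#' described in [sim_config()]'s documentation. The lag is applied as a
#' whole-sample shift (edge samples held at the first value) and the motor
#' noise is drawn per axis from the current RNG state, so reproducibility is
#' governed by the caller's seed.
#'
#' @param model a [participant_model()].
#' @param spec one stimulus bank row (needs `label` and the trial's
#'   `configuration` is taken from `configuration` argument).
#' @param effect_map planted multiplier table; must contain the
#'   (stimulus, configuration) cell.
#' @param timeline a [trial_timeline()].
#' @param configuration electrode configuration of this trial.
#' @param target,perturbation optional precomputed trajectories (shared
#'   across a cohort); generated from the timeline when omitted.
#' @param trial replicate index.
#' @return A `trial_record`.
#' @export
simulate_trial <- function(model, spec, effect_map, timeline,
                           configuration = spec$configuration,
                           target = NULL, perturbation = NULL, trial = 1L) {
  stopifnot(inherits(model, "participant_model"),
            inherits(timeline, "trial_timeline"))
  spec <- as.list(spec)
  if (is.null(target)) target <- make_target_trajectory(timeline)
  if (is.null(perturbation)) perturbation <- make_perturbation_trajectory(timeline)
  mult <- effect_multiplier(effect_map, spec$label, configuration)
  fs <- timeline$sample_rate
  n <- timeline$n_samples
  k <- round(model$lag * fs)
  sd <- model$base_noise_sd * mult
  cursor <- structure(
    list(
      x = model$gain * shift_with_edge_hold(target$x, k) + perturbation$x +
        lowpass_noise(n, sd, model$noise_bandwidth, fs),
      y = model$gain * shift_with_edge_hold(target$y, k) + perturbation$y +
        lowpass_noise(n, sd, model$noise_bandwidth, fs),
      sample_rate = fs
    ),
    class = "trajectory"
  )
  new_trial_record(model$participant_id, configuration, spec$label,
                   target, perturbation, cursor, trial = trial)
}

#' Simulate a cohort of tracking trials
#'
#' Generates the full crossed design: every participant performs one trial
#' per (configuration x bank stimulus), with `n_sham_trials` sham replicates
#' per configuration. Per-participant gains, lags and noise levels are drawn
#' once from the distributions documented below; each participant consumes an
#' independent RNG substream derived from the cohort seed, so adding an
#' eleventh participant leaves the first ten participants' data unchanged.
#'
#' Participant parameters: gain ~ lognormal(0, 0.05); lag ~ U(0.12, 0.25) s;
#' base_noise_sd ~ lognormal(log 0.15, 0.25) screen units; noise bandwidth
#' 2 Hz. Non-sham effect-map cells receive an additional per-participant
#' lognormal(0, `participant_heterogeneity_sd`) multiplier, so each
#' participant has their own realised optimal (stimulus, configuration).
#'
#' @param config a [sim_config()].
#' @return A list of class `gvs_cohort` with elements `trials` (list of
#'   `trial_record`s) and `truth` (planted ground truth: `participants`
#'   tibble, per-participant realised `effect` multipliers, and the seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  participant_seeds <- withr_seed(config$seed, {
    sample.int(.Machine$integer.max - 1L, config$n_participants)
  })
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  target <- make_target_trajectory(config$timeline)
  perturbation <- make_perturbation_trajectory(config$timeline)
  bank <- make_stimulus_bank("two_pole")  # labels/order; configuration set per trial

  one_participant <- function(i) {
    set.seed(participant_seeds[i])
    model <- participant_model(
      participant_id = ids[i],
      gain = stats::rlnorm(1, 0, 0.05),
      lag = stats::runif(1, 0.12, 0.25),
      base_noise_sd = stats::rlnorm(1, log(0.15), 0.25),
      noise_bandwidth = 2
    )
    map <- config$effect_map
    if ("participant_id" %in% names(map)) {
      map <- dplyr::filter(map, .data$participant_id == ids[i])
      stopifnot(nrow(map) > 0)
    }
    if (config$participant_heterogeneity_sd > 0) {
      pert <- stats::rlnorm(nrow(map), 0, config$participant_heterogeneity_sd)
      map$multiplier <- map$multiplier *
        ifelse(map$stimulus_label == "SHAM", 1, pert)
    }
    trials <- list()
    for (cfg in gvs_configurations()) {
      for (s in seq_len(nrow(bank))) {
        spec <- bank[s, ]
        reps <- if (spec$is_sham) config$n_sham_trials else 1L
        for (r in seq_len(reps)) {
          trials[[length(trials) + 1L]] <- simulate_trial(
            model, spec, map, config$timeline, configuration = cfg,
            target = target, perturbation = perturbation, trial = r
          )
        }
      }
    }
    list(model = model, effect = tibble::tibble(participant_id = ids[i],
                                                stimulus_label = map$stimulus_label,
                                                configuration = map$configuration,
                                                multiplier = map$multiplier),
         trials = trials)
  }

  per_part <- lapply(seq_len(config$n_participants), one_participant)
  participants <- dplyr::bind_rows(lapply(per_part, function(p) {
    tibble::tibble(participant_id = p$model$participant_id,
                   gain = p$model$gain, lag = p$model$lag,
                   base_noise_sd = p$model$base_noise_sd,
                   noise_bandwidth = p$model$noise_bandwidth)
  }))
  structure(
    list(
      trials = do.call(c, lapply(per_part, `[[`, "trials")),
      truth = list(participants = participants,
                   effect = dplyr::bind_rows(lapply(per_part, `[[`, "effect")),
                   seed = config$seed,
                   n_sham_trials = config$n_sham_trials)
    ),
    class = "gvs_cohort"
  )
}

#' Planted optimal condition per participant
#'
#' Reads the realised (post-heterogeneity) effect multipliers of a simulated
#' cohort and returns each participant's true optimal non-sham
#' (stimulus, configuration) cell — the ground truth that
#' [select_individualised()] should recover from the noisy trials.
#'
#' @param cohort a `gvs_cohort`.
#' @return A tibble with columns `participant_id`, `stimulus_label`,
#'   `configuration`, `multiplier`.
#' @export
planted_optima <- function(cohort) {
  stopifnot(inherits(cohort, "gvs_cohort"))
  cohort$truth$effect |>
    dplyr::filter(.data$stimulus_label != "SHAM") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::slice_min(.data$multiplier, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' @export
print.gvs_cohort <- function(x, ...) {
  cat(sprintf("<gvs_cohort> %d trials, %d participants (seed %d)\n",
              length(x$trials), nrow(x$truth$participants), x$truth$seed))
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s / %s / %s (trial %d): %d samples at %g Hz\n",
              x$participant_id, x$configuration, x$stimulus_label, x$trial,
              length(x$cursor$x), x$cursor$sample_rate))
  invisible(x)
}
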