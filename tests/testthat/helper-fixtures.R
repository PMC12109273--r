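# Shared fixtures: small timelines and cohorts so unit tests stay fast.

short_timeline <- function(duration = 10) {
  trial_timeline(trial_duration = duration, break_duration = 0,
                 sample_rate = 60)
}

# noiseless single trial: cursor is exactly gain * target + perturbation
noiseless_trial <- function(timeline = trial_timeline(), gain = 1,
                            stimulus = "GVS1", configuration = "two_pole") {
  bank <- make_stimulus_bank(configuration)
  model <- participant_model("P01", gain = gain, lag = 0, base_noise_sd = 0)
  map <- default_effect_map()
  simulate_trial(model, bank[bank$label == stimulus, ], map, timeline,
                 configuration = configuration)
}

# small noisy cohort for pipeline-level tests
small_cohort <- function(n = 2, seed = 11, duration = 10, ...) {
  simulate_cohort(sim_config(n_participants = n,
                             timeline = short_timeline(duration),
                             seed = seed, ...))
}

# a flat (null) effect map: every stimulus behaves like sham
null_effect_map <- function() {
  map <- default_effect_map()
  map$multiplier <- 1
  map
}

# per-participant effect maps with one planted optimal cell each
planted_participant_maps <- function(optima, contrast = 1.3) {
  dplyr::bind_rows(lapply(seq_len(nrow(optima)), function(i) {
    map <- planted_optimum_map(optima$stimulus_label[i],
                               optima$configuration[i], contrast = contrast)
    map$participant_id <- optima$participant_id[i]
    map
  }))
}
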