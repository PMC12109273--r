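test_that("noiseless trial reproduces gain * lagged target + perturbation exactly", {
  tl <- short_timeline(10)
  bank <- make_stimulus_bank("two_pole")
  model <- participant_model("P01", gain = 1.3, lag = 0.2, base_noise_sd = 0)
  trial <- simulate_trial(model, bank[1, ], default_effect_map(), tl,
                          configuration = "two_pole")
  k <- round(0.2 * 60)
  tgt <- make_target_trajectory(tl)
  per <- make_perturbation_trajectory(tl)
  lagged <- c(rep(tgt$x[1], k), tgt$x[1:(600 - k)])
  expect_equal(trial$cursor$x, 1.3 * lagged + per$x)
  # edge samples held at the first value
  expect_true(all(trial$cursor$x[1:k] == 1.3 * tgt$x[1] + per$x[1:k]))
})

test_that("planted noise multiplier scales the injected noise linearly", {
  tl <- short_timeline(30)
  bank <- make_stimulus_bank("two_pole")
  model <- participant_model("P01", gain = 1, lag = 0, base_noise_sd = 0.1)
  map <- default_effect_map()
  map$multiplier[map$stimulus_label == "GVS1"] <- 1
  map$multiplier[map$stimulus_label == "GVS2"] <- 2
  noise_of <- function(label, seed) {
    set.seed(seed)
    trial <- simulate_trial(model, bank[bank$label == label, ], map, tl,
                            configuration = "two_pole")
    trial$cursor$x - make_target_trajectory(tl)$x -
      make_perturbation_trajectory(tl)$x
  }
  # identical RNG stream: the ratio of planted noise SDs is exactly 2
  sd1 <- stats::sd(noise_of("GVS1", 99))
  sd2 <- stats::sd(noise_of("GVS2", 99))
  expect_equal(sd2 / sd1, 2, tolerance = 1e-12)
  # and the pipeline's residual SD sees the same ratio within 10%
  set.seed(99); t1 <- simulate_trial(model, bank[1, ], map, tl, "two_pole")
  set.seed(98); t2 <- simulate_trial(model, bank[2, ], map, tl, "two_pole")
  r1 <- mean(trial_errors(t1)$means)
  r2 <- mean(trial_errors(t2)$means)
  expect_equal(r2 / r1, 2, tolerance = 0.1)
})

test_that("unknown stimulus label fails the effect-map lookup", {
  tl <- short_timeline(10)
  model <- participant_model("P01")
  spec <- list(label = "GVS99", is_sham = FALSE)
  expect_error(
    simulate_trial(model, spec, default_effect_map(), tl, "two_pole"),
    "no unique entry"
  )
})

test_that("cohorts are reproducible and have the full crossed design", {
  c1 <- small_cohort(n = 2, seed = 21)
  c2 <- small_cohort(n = 2, seed = 21)
  expect_equal(length(c1$trials), 2 * 2 * 9)
  expect_identical(
    lapply(c1$trials, function(tr) tr$cursor$x),
    lapply(c2$trials, function(tr) tr$cursor$x)
  )
  expect_identical(c1$truth$effect, c2$truth$effect)

  # two sham replicates per configuration
  c3 <- simulate_cohort(sim_config(n_participants = 2,
                                   timeline = short_timeline(10),
                                   n_sham_trials = 2, seed = 21))
  expect_equal(length(c3$trials), 2 * 2 * 10)
  sham_trials <- Filter(function(tr) tr$stimulus_label == "SHAM", c3$trials)
  expect_equal(length(sham_trials), 2 * 2 * 2)
})

test_that("adding a participant does not perturb earlier participants' data", {
  c3 <- small_cohort(n = 3, seed = 33)
  c4 <- small_cohort(n = 4, seed = 33)
  keep <- vapply(c4$trials, function(tr) tr$participant_id %in%
                   c("P01", "P02", "P03"), logical(1))
  expect_identical(
    lapply(c3$trials, function(tr) tr$cursor$y),
    lapply(c4$trials[keep], function(tr) tr$cursor$y)
  )
})

test_that("mean tracking error is monotone in the planted multiplier", {
  tl <- short_timeline(15)
  bank <- make_stimulus_bank("two_pole")
  map <- default_effect_map()
  map$multiplier[map$stimulus_label == "GVS1"] <- 1
  map$multiplier[map$stimulus_label == "GVS2"] <- 1.5
  map$multiplier[map$stimulus_label == "GVS3"] <- 2
  model <- participant_model("P01", lag = 0.15, base_noise_sd = 0.15)
  n_monotone <- 0
  for (seed in 1:20) {
    set.seed(seed)
    errs <- vapply(c("GVS1", "GVS2", "GVS3"), function(lab) {
      trial <- simulate_trial(model, bank[bank$label == lab, ], map, tl,
                              "two_pole")
      mean(trial_errors(trial)$means)
    }, numeric(1))
    if (!is.unsorted(errs)) n_monotone <- n_monotone + 1
  }
  expect_gt(n_monotone, 10)  # majority sense over 20 seeds
})

test_that("planted optima are recoverable from the ground-truth sidecar", {
  optima <- tibble::tibble(
    participant_id = c("P01", "P02"),
    stimulus_label = c("GVS3", "GVS8"),
    configuration = c("two_pole", "three_pole")
  )
  cfg <- sim_config(n_participants = 2, timeline = short_timeline(10),
                    effect_map = planted_participant_maps(optima),
                    participant_heterogeneity_sd = 0, seed = 5)
  cohort <- simulate_cohort(cfg)
  found <- planted_optima(cohort)
  expect_equal(found$stimulus_label, optima$stimulus_label)
  expect_equal(found$configuration, optima$configuration)
})
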