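test_that("delta_err averages paired sub-trial differences with the stated sign", {
  expect_equal(delta_err(rep(1, 18), rep(1.5, 18)), -0.5)  # two-pole better
  expect_equal(delta_err(rep(2, 5), rep(2, 5)), 0)
  expect_equal(delta_err(c(1, 3), c(2, 2)), 0)
  expect_error(delta_err(1:3, 1:2), "same number")
  # antisymmetry
  set.seed(8)
  a <- runif(18); b <- runif(18)
  expect_equal(delta_err(a, b), -delta_err(b, a))
})

test_that("metrics_table pools sham replicates into one row per condition", {
  st <- tibble::tibble(
    participant_id = "P01",
    configuration = "two_pole",
    stimulus_label = c(rep("SHAM", 4), rep("GVS1", 2)),
    trial = c(1, 1, 2, 2, 1, 1),
    subtrial_index = c(1, 2, 1, 2, 1, 2),
    mean_err = c(1, 2, 3, 4, 5, 6)
  )
  mt <- metrics_table(st)
  expect_equal(nrow(mt), 2L)
  expect_equal(mt$mean_err[mt$stimulus_label == "SHAM"], 2.5)
  expect_equal(mt$mean_err[mt$stimulus_label == "GVS1"], 5.5)
})

test_that("individualised selection is the non-sham argmin with deterministic ties", {
  grid <- tidyr::expand_grid(
    participant_id = "P01",
    stimulus_label = c(paste0("GVS", 1:8), "SHAM"),
    configuration = gvs_configurations()
  )
  grid$mean_err <- 1
  grid$mean_err[grid$stimulus_label == "GVS3" &
                  grid$configuration == "two_pole"] <- 0.4
  grid$mean_err[grid$stimulus_label == "SHAM"] <- 0.1  # sham excluded
  choice <- select_individualised(grid, "P01")
  expect_equal(choice$stimulus_label, "GVS3")
  expect_equal(choice$configuration, "two_pole")
  expect_equal(choice$mean_err, 0.4)

  # exact tie: bank order first, then two-pole before three-pole
  tie <- grid
  tie$mean_err <- 1
  tie$mean_err[tie$stimulus_label == "GVS2" &
                 tie$configuration == "three_pole"] <- 0.5
  tie$mean_err[tie$stimulus_label == "GVS1" &
                 tie$configuration == "two_pole"] <- 0.5
  pick <- select_individualised(tie, "P01")
  expect_equal(pick$stimulus_label, "GVS1")
  expect_equal(pick$configuration, "two_pole")

  cfg_tie <- grid
  cfg_tie$mean_err <- 1
  cfg_tie$mean_err[cfg_tie$stimulus_label == "GVS5"] <- 0.5  # both configs
  expect_equal(select_individualised(cfg_tie, "P01")$configuration, "two_pole")

  expect_error(select_individualised(grid, "P99"), "unknown participant")
})

test_that("performance-improvement percentages follow their defining ratios", {
  expect_equal(pi_over_sham(1.25, 1), 25)
  expect_equal(pi_over_sham(1, 1), 0)
  expect_equal(pi_over_sham(1, 2), -50)
  expect_error(pi_over_sham(1, 0), "positive")

  expect_equal(pi_individualised(1.24, 1), 24)
  expect_equal(pi_individualised(2, 2), 0)
  expect_error(pi_individualised(1, -1), "positive")
  # strictly decreasing in the individualised error
  expect_gt(pi_individualised(1.5, 0.9), pi_individualised(1.5, 1.0))
})

test_that("improvement table mirrors the per-stimulus report structure", {
  cohort <- small_cohort(n = 5, seed = 17, duration = 15)
  st <- subtrial_error_table(cohort$trials)
  tab <- improvement_table(st)
  expect_equal(tab$stimulus_label, c(paste0("GVS", 1:8), "SHAM"))
  expect_equal(names(tab), c("stimulus_label",
                             "improvement_individualised_pct",
                             "improvement_over_sham_pct"))
  # sham against itself is exactly 0%
  expect_equal(tab$improvement_over_sham_pct[tab$stimulus_label == "SHAM"], 0)
  # individualised choice is each participant's minimum, so its improvement
  # over any single stimulus averaged across configurations is positive
  expect_true(all(tab$improvement_individualised_pct > 0))
})

test_that("cross-configuration means average the two per-config means", {
  st <- tibble::tibble(
    participant_id = "P01",
    configuration = rep(gvs_configurations(), each = 2),
    stimulus_label = "GVS1",
    trial = 1,
    subtrial_index = rep(1:2, 2),
    mean_err = c(1, 2, 3, 5)
  )
  cc <- cross_config_means(st)
  expect_equal(cc$mean_err, mean(c(mean(c(1, 2)), mean(c(3, 5)))))
})

test_that("delta_err_table pairs configurations by sub-trial", {
  cohort <- small_cohort(n = 2, seed = 13)
  st <- subtrial_error_table(cohort$trials)
  dt <- delta_err_table(st)
  expect_equal(nrow(dt), 2 * 9)
  one <- st[st$participant_id == "P01" & st$stimulus_label == "GVS1", ]
  manual <- delta_err(one$mean_err[one$configuration == "two_pole"],
                      one$mean_err[one$configuration == "three_pole"])
  expect_equal(dt$delta_err[dt$participant_id == "P01" &
                              dt$stimulus_label == "GVS1"], manual)
})
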