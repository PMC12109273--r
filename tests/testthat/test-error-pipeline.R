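test_that("Hilbert quadrature of a cosine is the matching sine", {
  fs <- 60
  for (freq in c(0.1, 0.5, 2)) {
    n <- fs * 10  # integer number of periods for all three frequencies
    t <- (0:(n - 1)) / fs
    q <- hilbert_quadrature(cos(2 * pi * freq * t))
    inner <- 3:(n - 2)  # exclude 2 samples at each edge
    expect_lt(max(abs(q[inner] - sin(2 * pi * freq * t)[inner])), 1e-6)
  }
})

test_that("Hilbert quadrature degenerate inputs", {
  expect_equal(hilbert_quadrature(numeric(16)), numeric(16))
  expect_lt(max(abs(hilbert_quadrature(rep(3.7, 100)))), 1e-12)
  expect_error(hilbert_quadrature(c(1, 2, 3)), "length")
  expect_error(hilbert_quadrature(c(1, 2, NA, 4)), "finite")
  # odd lengths use the odd-branch analytic construction
  t <- (0:299) / 60
  q <- hilbert_quadrature(cos(2 * pi * 0.2 * t)[1:299])
  expect_true(is.numeric(q) && length(q) == 299)
})

test_that("regress_out removes exact linear combinations of the design", {
  t <- (0:599) / 60
  lx <- sin(2 * pi * 0.075 * t)
  hx <- hilbert_quadrature(lx)
  cursor <- 2 * lx + 3 * hx + 5
  res <- regress_out(cursor, list(lx, hx))
  expect_lt(max(abs(res)), 1e-8 * max(abs(cursor)))
})

test_that("regress_out matches the explicit normal-equations solution", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    p <- sample(1:4, 1)
    regs <- replicate(p, rnorm(n), simplify = FALSE)
    y <- rnorm(n)
    res <- regress_out(y, regs)
    x <- cbind(1, do.call(cbind, regs))
    beta <- solve(t(x) %*% x, t(x) %*% y)  # brute-force oracle
    expect_equal(res, as.numeric(y - x %*% beta), tolerance = 1e-8)
  }
})

test_that("regress_out leaves regressor-orthogonal signal untouched and is orthogonal to design", {
  set.seed(7)
  n <- 600
  t <- (0:(n - 1)) / 60
  lx <- sin(2 * pi * 0.075 * t)
  noise <- rnorm(n)
  noise_orth <- regress_out(noise, list(lx))  # orthogonalised noise
  res <- regress_out(noise_orth, list(lx))
  expect_gt(stats::cor(res, noise_orth), 0.999)
  # residual mean ~ 0 and orthogonality to every regressor
  expect_lt(abs(mean(res)), 1e-9 * stats::sd(noise_orth))
  expect_lt(abs(sum(res * lx)), 1e-6 * sqrt(sum(res^2) * sum(lx^2)))
})

test_that("regress_out drops collinear columns with a warning", {
  set.seed(1)
  x1 <- rnorm(100)
  expect_warning(res <- regress_out(rnorm(100), list(x1, 2 * x1)),
                 "rank-deficient")
  expect_length(res, 100L)
})

test_that("error time course is the pointwise Euclidean residual magnitude", {
  expect_equal(error_timecourse(3, 4), 5)
  expect_equal(error_timecourse(0, 0), 0)
  c_vals <- c(0.3, 1.7)
  expect_equal(error_timecourse(c_vals, c_vals), c_vals * sqrt(2))
  expect_error(error_timecourse(1:3, 1:2))
})

test_that("sub-trial segmentation uses quarter-period segments with floor rule", {
  se <- segment_subtrials(rep(1, 2700), sample_rate = 60, target_y_freq = 0.1)
  expect_equal(se$segment_length_s, 2.5)
  expect_equal(se$n_subtrials, 18L)
  expect_length(se$means, 18L)

  # constant error -> every sub-trial mean equals the constant
  se_c <- segment_subtrials(rep(0.7, 2700), 60)
  expect_true(all(se_c$means == 0.7))

  # 46 s trial: trailing 1 s discarded, still 18 sub-trials
  se46 <- segment_subtrials(rep(1, 46 * 60), 60)
  expect_equal(se46$n_subtrials, 18L)

  # segment means are plain segment averages
  err <- seq_len(300) / 300
  se2 <- segment_subtrials(err, 60)
  expect_equal(se2$means, c(mean(err[1:150]), mean(err[151:300])))

  expect_error(segment_subtrials(rep(1, 100), 60), "shorter")
})

test_that("pipeline is scale equivariant", {
  trial <- noiseless_trial(short_timeline(10))
  set.seed(3)
  trial$cursor$x <- trial$cursor$x + rnorm(600, sd = 0.1)
  trial$cursor$y <- trial$cursor$y + rnorm(600, sd = 0.1)
  base <- trial_errors(trial)
  k <- 3.7
  scaled <- trial
  for (f in c("target", "perturbation", "cursor")) {
    scaled[[f]]$x <- k * scaled[[f]]$x
    scaled[[f]]$y <- k * scaled[[f]]$y
  }
  expect_equal(trial_errors(scaled)$means, k * base$means, tolerance = 1e-10)
})

test_that("noiseless zero-lag trials give vanishing sub-trial means", {
  for (gain in c(1, 0.8)) {
    trial <- noiseless_trial(trial_timeline(), gain = gain)
    se <- trial_errors(trial)
    expect_lt(max(se$means), 1e-8)  # target amplitude is 1
  }
})

test_that("target-only regressor set leaves the perturbation in the residual", {
  trial <- noiseless_trial(short_timeline(10))
  se_full <- trial_errors(trial, regressor_set = "full")
  se_tgt <- trial_errors(trial, regressor_set = "target_only")
  expect_lt(max(se_full$means), 1e-8)
  expect_gt(mean(se_tgt$means), 0.1)  # perturbation amplitude 0.25 remains
})

test_that("subtrial_error_table stacks per-trial means in long format", {
  cohort <- small_cohort(n = 2, seed = 5)
  st <- subtrial_error_table(cohort$trials)
  expect_equal(names(st), c("participant_id", "configuration",
                            "stimulus_label", "trial", "subtrial_index",
                            "mean_err"))
  # 2 participants x 2 configs x 9 stimuli x 4 sub-trials (10 s trials)
  expect_equal(nrow(st), 2 * 2 * 9 * 4)
  expect_true(all(st$mean_err >= 0))
  one <- trial_errors(cohort$trials[[1]])
  expect_equal(st$mean_err[1:4], one$means)
})
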