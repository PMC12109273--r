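# Tracking-error pipeline: regress the deterministic Lissajous curves (and
# their Hilbert quadratures) out of the cursor path, form the Euclidean
# residual magnitude ErrR, and average it within 2.5 s sub-trials.

#' Hilbert quadrature of a real signal
#'
#' Imaginary part of the discrete analytic signal, computed by the standard
#' FFT construction: positive frequencies doubled, negative frequencies
#' zeroed (DC and, for even length, the Nyquist bin kept once). For a pure
#' cosine over an integer number of periods the quadrature is the matching
#' sine; a time-shifted sinusoid lies in the span of the original signal and
#' its quadrature, which is what lets the regression absorb a visuomotor lag.
#'
#' @param signal numeric vector, length >= 4, finite values.
#' @return Numeric vector of the same length.
#' @examples
#' t <- (0:599) / 60
#' q <- hilbert_quadrature(cos(2 * pi * 0.5 * t))  # ~ sin(2*pi*0.5*t)
#' @export
hilbert_quadrature <- function(signal) {
  if (!is.numeric(signal) || length(signal) < 4L) {
    stop("`signal` must be a numeric vector of length >= 4", call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("`signal` must be finite", call. = FALSE)
  }
  n <- length(signal)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(h * stats::fft(signal), inverse = TRUE) / n
  Im(analytic)
}

#' Regress nuisance trajectories out of one cursor axis
#'
#' Ordinary-least-squares residuals of `cursor_axis` on an intercept plus the
#' given regressors. This removes the deterministic task structure (target
#' and perturbation Lissajous components and their quadratures) from the
#' cursor path, leaving the participant's tracking error. Collinear columns
#' are dropped (rightmost first) with a warning rather than failing.
#'
#' @param cursor_axis numeric vector, one cursor coordinate over the trial.
#' @param regressors a list of numeric vectors, each the same length as
#'   `cursor_axis`, or a numeric matrix with those columns.
#' @return Numeric residual vector, orthogonal to the intercept and to every
#'   retained regressor.
#' @examples
#' t <- (0:299) / 60
#' tgt <- sin(2 * pi * 0.1 * t)
#' res <- regress_out(2 * tgt + rnorm(300, sd = 0.1), list(tgt))
#' @export
regress_out <- function(cursor_axis, regressors) {
  if (is.matrix(regressors)) {
    regressors <- lapply(seq_len(ncol(regressors)), function(j) regressors[, j])
  }
  stopifnot(is.numeric(cursor_axis), is.list(regressors), length(regressors) >= 1)
  n <- length(cursor_axis)
  if (!all(vapply(regressors, length, integer(1)) == n)) {
    stop("all regressors must have the same length as `cursor_axis`",
         call. = FALSE)
  }
  x <- cbind(intercept = 1, do.call(cbind, regressors))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
    warning(sprintf("design is rank-deficient; dropping %d collinear column(s)",
                    ncol(x) - qr_x$rank), call. = FALSE)
    qr_x <- qr(x[, keep, drop = FALSE])
  }
  qr.resid(qr_x, cursor_axis)
}

#' Pointwise tracking-error magnitude
#'
#' The tracking-error time course: the Euclidean magnitude of the X and Y
#' regression residuals at each time point,
#' \deqn{ErrR_i = \sqrt{ErrX_i^2 + ErrY_i^2}.}
#'
#' @param err_x,err_y residual vectors of equal length (from [regress_out()]).
#' @return Non-negative numeric vector.
#' @examples
#' error_timecourse(3, 4)  # 5
#' @export
error_timecourse <- function(err_x, err_y) {
  stopifnot(is.numeric(err_x), is.numeric(err_y),
            length(err_x) == length(err_y))
  sqrt(err_x^2 + err_y^2)
}

#' Segment the error time course into sub-trials
#'
#' Splits the tracking-error time course into consecutive non-overlapping
#' sub-trials whose duration is one quarter of the period of the target
#' Lissajous Y frequency (0.1 Hz gives 2.5 s, hence 18 sub-trials of 150
#' samples in a 45 s trial at 60 Hz), and averages the error within each. A
#' trailing partial segment is discarded. Sub-trials are the averaging and
#' repeated-measures unit of all downstream statistics.
#'
#' @param err_r numeric vector, the pointwise error magnitude.
#' @param sample_rate sampling rate in Hz.
#' @param target_y_freq target Lissajous Y frequency in Hz (default 0.1).
#' @return An object of class `subtrial_errors`: list with `means` (one mean
#'   error per sub-trial), `segment_length_s`, and `n_subtrials`.
#' @examples
#' se <- segment_subtrials(runif(2700), sample_rate = 60)
#' se$n_subtrials  # 18
#' @export
segment_subtrials <- function(err_r, sample_rate, target_y_freq = 0.1) {
  stopifnot(is.numeric(err_r), sample_rate > 0, target_y_freq > 0)
  segment_length_s <- (1 / target_y_freq) / 4
  seg_n <- round(segment_length_s * sample_rate)
  if (seg_n < 1 || length(err_r) < seg_n) {
    stop("error time course is shorter than one sub-trial segment",
         call. = FALSE)
  }
  n_sub <- floor(length(err_r) / seg_n)
  idx <- rep(seq_len(n_sub), each = seg_n)
  means <- as.numeric(tapply(err_r[seq_len(n_sub * seg_n)], idx, mean))
  structure(
    list(means = means, segment_length_s = segment_length_s,
         n_subtrials = n_sub),
    class = "subtrial_errors"
  )
}

# Per-axis nuisance designs for one trial geometry, QR-factorised once so a
# whole cohort sharing the same target/perturbation can be processed without
# refactorising. regressor_set "full" uses target + perturbation curves and
# both quadratures; "target_only" the narrower reading.
trial_design <- function(target, perturbation,
                         regressor_set = c("full", "target_only")) {
  regressor_set <- match.arg(regressor_set)
  stopifnot(inherits(target, "trajectory"), inherits(perturbation, "trajectory"),
            length(target$x) == length(perturbation$x))
  axis_design <- function(tgt, per) {
    cols <- list(tgt, hilbert_quadrature(tgt))
    if (regressor_set == "full") {
      cols <- c(cols, list(per, hilbert_quadrature(per)))
    }
    qr(cbind(1, do.call(cbind, cols)))
  }
  structure(
    list(qr_x = axis_design(target$x, perturbation$x),
         qr_y = axis_design(target$y, perturbation$y),
         regressor_set = regressor_set,
         n = length(target$x)),
    class = "trial_design"
  )
}

#' Tracking error of one trial
#'
#' Runs the full error pipeline on one trial: per-axis OLS regression of the
#' cursor on the deterministic Lissajous regressors (target and, by default,
#' perturbation, each with its Hilbert quadrature, plus an intercept),
#' pointwise residual magnitude, and sub-trial segmentation. Regressions are
#' per axis: the X cursor coordinate on X regressors only, Y on Y only. The
#' quadratures are computed on the full trial before segmentation, so edge
#' effects are confined to the trial ends rather than every segment
#' boundary.
#'
#' @param trial a `trial_record` (see [simulate_trial()] or [read_trials()]).
#' @param regressor_set `"full"` (target + perturbation curves and their
#'   quadratures) or `"target_only"`.
#' @param target_y_freq target Lissajous Y frequency in Hz, setting the
#'   sub-trial length.
#' @param design optional precomputed per-axis design (from the internal
#'   `trial_design()` helper) shared across trials
#'   with identical target/perturbation geometry (a cohort-level speed-up).
#' @return A `subtrial_errors` object.
#' @export
trial_errors <- function(trial, regressor_set = c("full", "target_only"),
                         target_y_freq = 0.1, design = NULL) {
  stopifnot(inherits(trial, "trial_record"))
  regressor_set <- match.arg(regressor_set)
  if (is.null(design)) {
    design <- trial_design(trial$target, trial$perturbation, regressor_set)
  }
  stopifnot(inherits(design, "trial_design"), design$n == length(trial$cursor$x))
  err_x <- qr.resid(design$qr_x, trial$cursor$x)
  err_y <- qr.resid(design$qr_y, trial$cursor$y)
  segment_subtrials(error_timecourse(err_x, err_y),
                    sample_rate = trial$cursor$sample_rate,
                    target_y_freq = target_y_freq)
}

#' Sub-trial error table for a set of trials
#'
#' Applies [trial_errors()] to every trial and stacks the per-sub-trial mean
#' errors into the long table consumed by the metrics and statistics layers.
#' Trials sharing one trial geometry reuse a single factorised design.
#'
#' @param trials list of `trial_record`s.
#' @inheritParams trial_errors
#' @return A tibble with columns `participant_id`, `configuration`,
#'   `stimulus_label`, `trial`, `subtrial_index` (1-based), `mean_err`.
#' @export
subtrial_error_table <- function(trials,
                                 regressor_set = c("full", "target_only"),
                                 target_y_freq = 0.1) {
  regressor_set <- match.arg(regressor_set)
  stopifnot(length(trials) >= 1)
  design <- trial_design(trials[[1]]$target, trials[[1]]$perturbation,
                         regressor_set)
  shared <- function(trial) {
    length(trial$cursor$x) == design$n &&
      identical(trial$target$x[1:2], trials[[1]]$target$x[1:2])
  }
  rows <- lapply(trials, function(trial) {
    d <- if (shared(trial)) design else NULL
    se <- trial_errors(trial, regressor_set, target_y_freq, design = d)
    tibble::tibble(
      participant_id = trial$participant_id,
      configuration = trial$configuration,
      stimulus_label = trial$stimulus_label,
      trial = trial$trial,
      subtrial_index = seq_len(se$n_subtrials),
      mean_err = se$means
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.subtrial_errors <- function(x, ...) {
  cat(sprintf("<subtrial_errors> %d sub-trials of %g s; mean ErrR %.4g\n",
              x$n_subtrials, x$segment_length_s, mean(x$means)))
  invisible(x)
}
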