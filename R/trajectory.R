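# Deterministic Lissajous trajectories for the target and the cursor
# perturbation, and the trial timeline.

# task constants: Lissajous frequencies (Hz) of the pursuit target and of the
# additive cursor perturbation, and the trial timing
.target_freqs <- c(x = 0.075, y = 0.1)
.perturbation_freqs <- c(x = 0.14, y = 0.21)

#' Trial timeline
#'
#' Timing of one tracking trial: 45 s of tracking (and stimulation) sampled
#' at 60 Hz, followed by a 15 s break with no stimulus. The break carries no
#' samples; it is retained for protocol documentation.
#'
#' @param trial_duration tracking duration in seconds (> 0).
#' @param break_duration inter-trial break in seconds (>= 0).
#' @param sample_rate display/cursor sampling rate in Hz (> 0).
#' @return A list of class `trial_timeline`.
#' @examples
#' trial_timeline()
#' @export
trial_timeline <- function(trial_duration = 45, break_duration = 15,
                           sample_rate = 60) {
  stopifnot(trial_duration > 0, break_duration >= 0, sample_rate > 0)
  structure(
    list(trial_duration = trial_duration, break_duration = break_duration,
         sample_rate = sample_rate,
         n_samples = round(trial_duration * sample_rate)),
    class = "trial_timeline"
  )
}

#' Sampled Lissajous trajectory
#'
#' Evaluates the parametric curve
#' \deqn{x(t) = a_x \sin(2\pi f_x t + \phi_x), \quad
#'       y(t) = a_y \sin(2\pi f_y t + \phi_y)}
#' at `t = k / sample_rate`, `k = 0, ..., N-1` with
#' `N = round(duration * sample_rate)`.
#'
#' @param freq_x,freq_y frequencies in Hz (> 0).
#' @param duration duration in seconds (> 0).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param amp_x,amp_y amplitudes in screen units (>= 0).
#' @param phase_x,phase_y phases in radians.
#' @return An object of class `trajectory`: list with numeric `x`, `y` and
#'   `sample_rate`.
#' @examples
#' tr <- lissajous(0.075, 0.1, duration = 45, sample_rate = 60)
#' length(tr$x)
#' @export
lissajous <- function(freq_x, freq_y, duration, sample_rate,
                      amp_x = 1, amp_y = 1, phase_x = 0, phase_y = 0) {
  stopifnot(freq_x > 0, freq_y > 0, duration > 0, sample_rate > 0,
            amp_x >= 0, amp_y >= 0)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  structure(
    list(
      x = amp_x * sin(2 * pi * freq_x * t + phase_x),
      y = amp_y * sin(2 * pi * freq_y * t + phase_y),
      sample_rate = sample_rate
    ),
    class = "trajectory"
  )
}

#' Target and perturbation trajectories of the tracking task
#'
#' `make_target_trajectory()` generates the path of the target ring: a
#' Lissajous curve at 0.075 Hz (X) and 0.1 Hz (Y), invisible to the
#' participant. `make_perturbation_trajectory()` generates the smaller
#' Lissajous curve added to the cursor position (0.14 Hz X, 0.21 Hz Y),
#' with amplitude `amp_ratio` times the target amplitude (default 0.25).
#' Amplitudes are in abstract screen units centred at zero; the error
#' pipeline is invariant to their absolute scale.
#'
#' @param timeline a [trial_timeline()].
#' @param amplitude target amplitude in screen units.
#' @param amp_ratio perturbation/target amplitude ratio.
#' @return A `trajectory`.
#' @examples
#' tl <- trial_timeline()
#' tgt <- make_target_trajectory(tl)
#' per <- make_perturbation_trajectory(tl)
#' @export
make_target_trajectory <- function(timeline, amplitude = 1) {
  stopifnot(inherits(timeline, "trial_timeline"))
  lissajous(.target_freqs[["x"]], .target_freqs[["y"]],
            duration = timeline$trial_duration,
            sample_rate = timeline$sample_rate,
            amp_x = amplitude, amp_y = amplitude)
}

#' @rdname make_target_trajectory
#' @export
make_perturbation_trajectory <- function(timeline, amplitude = 1,
                                         amp_ratio = 0.25) {
  stopifnot(inherits(timeline, "trial_timeline"))
  lissajous(.perturbation_freqs[["x"]], .perturbation_freqs[["y"]],
            duration = timeline$trial_duration,
            sample_rate = timeline$sample_rate,
            amp_x = amplitude * amp_ratio, amp_y = amplitude * amp_ratio)
}

#' Convert a trajectory to a tibble / write as delimited text
#'
#' @param trajectory a `trajectory`.
#' @param path file path for `write_trajectory`.
#' @return A tibble with columns `time_s`, `x`, `y`.
#' @export
trajectory_tibble <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  n <- length(trajectory$x)
  tibble::tibble(
    time_s = (seq_len(n) - 1) / trajectory$sample_rate,
    x = trajectory$x,
    y = trajectory$y
  )
}

#' @rdname trajectory_tibble
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(trajectory_tibble(trajectory), path)
  invisible(path)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples at %g Hz\n", length(x$x), x$sample_rate))
  invisible(x)
}

#' @export
print.trial_timeline <- function(x, ...) {
  cat(sprintf("<trial_timeline> %g s trial + %g s break at %g Hz (%d samples)\n",
              x$trial_duration, x$break_duration, x$sample_rate, x$n_samples))
  invisible(x)
}
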