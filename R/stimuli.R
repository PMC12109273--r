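# Amplitude-modulated GVS stimulus bank, waveform synthesis, and the
# staircase-derived per-participant amplitude.

#: envelope / carrier frequency pairs (Hz) of the fixed stimulus bank
.gvs_bank_freqs <- list(
  GVS1 = c(10, 30),
  GVS2 = c(10, 60),
  GVS3 = c(20, 60),
  GVS4 = c(20, 110),
  GVS5 = c(30, 75),
  GVS6 = c(50, 110),
  GVS7 = c(70, 145),
  GVS8 = c(30, 110)
)

#' Electrode configurations
#'
#' The two electrode montages compared by the pipeline: `two_pole`
#' (electrodes over both mastoid processes) and `three_pole` (mastoids plus
#' temples).
#'
#' @export
gvs_configurations <- function() c("two_pole", "three_pole")

#' The amplitude-modulated GVS stimulus bank
#'
#' Returns the fixed bank of eight amplitude-modulated (AM) stimuli plus the
#' sham (zero-current) condition for one electrode configuration. Each AM
#' stimulus is an envelope/carrier frequency pair in Hz; the sham condition
#' delivers no current. The bank order is stable: GVS1 to GVS8, then SHAM.
#'
#' @param configuration electrode configuration, `"two_pole"` or
#'   `"three_pole"`.
#' @param amplitude stimulation current amplitude in mA applied to every
#'   non-sham stimulus (typically the participant's subthreshold amplitude
#'   from [optimal_amplitude()]). Sham always has amplitude 0.
#'
#' @return A tibble with one row per stimulus and columns `label`,
#'   `envelope_freq` (Hz), `carrier_freq` (Hz), `amplitude` (mA),
#'   `configuration`, `is_sham`.
#'
#' @examples
#' make_stimulus_bank("two_pole", amplitude = 0.54)
#' @export
make_stimulus_bank <- function(configuration = c("two_pole", "three_pole"),
                               amplitude = 1) {
  configuration <- match.arg(configuration)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  labels <- names(.gvs_bank_freqs)
  env <- unname(vapply(.gvs_bank_freqs, `[`, numeric(1), 1L))
  car <- unname(vapply(.gvs_bank_freqs, `[`, numeric(1), 2L))
  tibble::tibble(
    label = c(labels, "SHAM"),
    envelope_freq = c(env, 0),
    carrier_freq = c(car, 0),
    amplitude = c(rep(amplitude, length(labels)), 0),
    configuration = configuration,
    is_sham = c(rep(FALSE, length(labels)), TRUE)
  )
}

#' Synthesise an amplitude-modulated stimulus waveform
#'
#' Produces the sampled current waveform of one bank stimulus. The AM form is
#' a suppressed-carrier product of sines,
#' \deqn{s(t) = A \, ((1-m) + m \sin(2\pi f_e t)) \, \sin(2\pi f_c t),}
#' with envelope frequency \eqn{f_e}, carrier frequency \eqn{f_c}, amplitude
#' \eqn{A} (mA) and modulation depth \eqn{m} (default 1, i.e. the pure
#' product of sines whose spectrum concentrates at the sidebands
#' \eqn{f_c \pm f_e}). A sham spec yields an identically zero waveform.
#'
#' A warning is emitted when `sample_rate < 2 * carrier_freq`: such a
#' waveform is aliased and should not be used for spectral analysis. The
#' default synthesis rate of 600 Hz clears Nyquist for every carrier in the
#' bank.
#'
#' @param spec one bank row (a one-row data frame or a named list with
#'   `label`, `envelope_freq`, `carrier_freq`, `amplitude`, `is_sham`).
#' @param duration waveform duration in seconds (> 0).
#' @param sample_rate sampling rate in Hz (> 0); default 600.
#' @param modulation_depth modulation depth `m` in `[0, 1]`.
#'
#' @return An object of class `gvs_waveform`: a list with `samples` (mA),
#'   `sample_rate` (Hz), `duration` (s), and the originating `label`.
#'
#' @examples
#' bank <- make_stimulus_bank("two_pole")
#' w <- synthesize_am_stimulus(bank[bank$label == "GVS8", ], duration = 1)
#' max(abs(w$samples))
#' @export
synthesize_am_stimulus <- function(spec, duration, sample_rate = 600,
                                   modulation_depth = 1) {
  spec <- as.list(spec)
  stopifnot(
    is.numeric(duration), length(duration) == 1L, duration > 0,
    is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0,
    modulation_depth >= 0, modulation_depth <= 1
  )
  n <- round(duration * sample_rate)
  t <- seq_len(n) / sample_rate - 1 / sample_rate
  if (isTRUE(spec$is_sham)) {
    samples <- numeric(n)
  } else {
    if (sample_rate < 2 * spec$carrier_freq) {
      warning(sprintf(
        "sample_rate %g Hz is below Nyquist for carrier %g Hz; waveform is aliased",
        sample_rate, spec$carrier_freq
      ), call. = FALSE)
    }
    m <- modulation_depth
    envelope <- (1 - m) + m * sin(2 * pi * spec$envelope_freq * t)
    samples <- spec$amplitude * envelope * sin(2 * pi * spec$carrier_freq * t)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, duration = duration,
         label = spec$label),
    class = "gvs_waveform"
  )
}

#' Ascending-staircase sensory threshold
#'
#' Simulates / drives a single ascending staircase run: the current starts at
#' `base` mA and increases in steps of `step` mA until `perception(current)`
#' first returns `TRUE`. The returned value is the sensory threshold — the
#' smallest tested current that is perceived.
#'
#' @param perception a monotone predicate of current (mA): `FALSE` below the
#'   participant's threshold, `TRUE` at or above it.
#' @param base starting current in mA (> 0); default 0.1.
#' @param step increment in mA (> 0); default 0.1.
#' @param max_steps abort after this many increments without perception.
#'
#' @return Threshold current in mA.
#' @examples
#' staircase_threshold(function(c) c >= 0.55)
#' @export
staircase_threshold <- function(perception, base = 0.1, step = 0.1,
                                max_steps = 100) {
  stopifnot(is.function(perception), base > 0, step > 0, max_steps >= 1)
  current <- base
  for (k in seq_len(max_steps)) {
    if (isTRUE(perception(current))) return(current)
    current <- base + k * step
  }
  stop("staircase did not converge within ", max_steps,
       " steps (no perceived current)", call. = FALSE)
}

#' Subthreshold stimulation amplitude
#'
#' The stimulation amplitude used for all of a participant's trials in one
#' electrode configuration: 90% of the sensory threshold found by
#' [staircase_threshold()], so that the delivered current is imperceptible.
#' Thresholds are determined independently per configuration.
#'
#' @param threshold sensory threshold in mA (> 0).
#' @return 0.9 * threshold, in mA.
#' @examples
#' optimal_amplitude(0.6)
#' @export
optimal_amplitude <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    stop("`threshold` must be a single positive current in mA", call. = FALSE)
  }
  0.9 * threshold
}

#' Write a stimulus bank to JSON / read it back
#'
#' @param bank tibble from [make_stimulus_bank()].
#' @param path file path.
#' @return `read_stimulus_bank` returns the bank tibble.
#' @export
write_stimulus_bank <- function(bank, path) {
  jsonlite::write_json(bank, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_bank
#' @export
read_stimulus_bank <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a waveform as two-column delimited text
#'
#' Columns are `time_s` and `current_mA`.
#'
#' @param waveform a `gvs_waveform`.
#' @param path file path.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "gvs_waveform"))
  n <- length(waveform$samples)
  readr::write_csv(
    tibble::tibble(
      time_s = (seq_len(n) - 1) / waveform$sample_rate,
      current_mA = waveform$samples
    ),
    path
  )
  invisible(path)
}

#' @export
print.gvs_waveform <- function(x, ...) {
  cat(sprintf("<gvs_waveform> %s: %d samples at %g Hz (%.3g s), peak %.4g mA\n",
              x$label, length(x$samples), x$sample_rate, x$duration,
              max(abs(x$samples))))
  invisible(x)
}
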