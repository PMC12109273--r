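# Comparison metrics: per-condition mean tracking error, the two-pole minus
# three-pole difference, individualised-stimulus selection, and the
# performance-improvement percentages.

#' Per-condition mean tracking error
#'
#' Aggregates a sub-trial error table (from [subtrial_error_table()]) to one
#' row per (participant, stimulus, configuration). Replicate sham trials are
#' pooled before averaging, so each condition contributes a single mean
#' error. `cross_config_means()` further averages each participant's
#' per-stimulus error across the two electrode configurations — the inputs
#' of the improvement percentages.
#'
#' @param subtrials long tibble with columns `participant_id`,
#'   `configuration`, `stimulus_label`, `subtrial_index`, `mean_err` (an
#'   optional `trial` column marks sham replicates).
#' @return A tibble with one row per condition and column `mean_err`.
#' @export
metrics_table <- function(subtrials) {
  stopifnot(all(c("participant_id", "configuration", "stimulus_label",
                  "mean_err") %in% names(subtrials)))
  subtrials |>
    dplyr::group_by(.data$participant_id, .data$stimulus_label,
                    .data$configuration) |>
    dplyr::summarise(mean_err = mean(.data$mean_err),
                     n_subtrials = dplyr::n(), .groups = "drop")
}

#' @rdname metrics_table
#' @export
cross_config_means <- function(subtrials) {
  metrics_table(subtrials) |>
    dplyr::group_by(.data$participant_id, .data$stimulus_label) |>
    dplyr::summarise(mean_err = mean(.data$mean_err), .groups = "drop")
}

#' Two-pole minus three-pole error difference
#'
#' Mean over paired sub-trials of (two-pole error - three-pole error) for one
#' condition. Negative values indicate better performance (lower error) with
#' the two-pole configuration.
#'
#' @param two_pole,three_pole `subtrial_errors` objects or plain numeric
#'   vectors of per-sub-trial mean errors, paired by sub-trial index and of
#'   equal length.
#' @return A single number in screen units.
#' @examples
#' delta_err(c(1, 3), c(2, 2))  # 0
#' @export
delta_err <- function(two_pole, three_pole) {
  m2 <- if (inherits(two_pole, "subtrial_errors")) two_pole$means else two_pole
  m3 <- if (inherits(three_pole, "subtrial_errors")) three_pole$means else three_pole
  stopifnot(is.numeric(m2), is.numeric(m3))
  if (length(m2) != length(m3)) {
    stop("the two configurations must have the same number of sub-trials",
         call. = FALSE)
  }
  mean(m2 - m3)
}

#' Per-condition error-difference table
#'
#' [delta_err()] applied to every (participant, stimulus): for each, the mean
#' over paired sub-trials of the two-pole minus three-pole error, with its
#' standard error across sub-trials.
#'
#' @inheritParams metrics_table
#' @return A tibble with columns `participant_id`, `stimulus_label`,
#'   `delta_err`, `se`.
#' @export
delta_err_table <- function(subtrials) {
  key <- c("participant_id", "stimulus_label", "subtrial_index")
  if ("trial" %in% names(subtrials)) key <- c(key, "trial")
  wide <- subtrials |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(key),
                       names_from = "configuration",
                       values_from = "mean_err")
  stopifnot(all(c("two_pole", "three_pole") %in% names(wide)))
  wide |>
    dplyr::group_by(.data$participant_id, .data$stimulus_label) |>
    dplyr::summarise(
      delta_err = mean(.data$two_pole - .data$three_pole),
      se = stats::sd(.data$two_pole - .data$three_pole) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Individualised stimulus selection
#'
#' The individualised stimulus of a participant is the non-sham
#' (stimulus, configuration) pair that produced the least mean tracking
#' error across all GVS stimuli and both pole configurations. Exact ties are
#' broken deterministically: bank order GVS1..GVS8 first, then two-pole
#' before three-pole.
#'
#' @param table per-condition tibble from [metrics_table()].
#' @param participant_id participant to select for; omit to select for every
#'   participant in the table.
#' @return A tibble with one row per participant: `participant_id`,
#'   `stimulus_label`, `configuration`, `mean_err`.
#' @export
select_individualised <- function(table, participant_id = NULL) {
  stopifnot(all(c("participant_id", "stimulus_label", "configuration",
                  "mean_err") %in% names(table)))
  if (!is.null(participant_id)) {
    if (!participant_id %in% table$participant_id) {
      stop("unknown participant: ", participant_id, call. = FALSE)
    }
    table <- table[table$participant_id %in% participant_id, ]
  }
  bank_order <- c(names(.gvs_bank_freqs))
  candidates <- table |>
    dplyr::filter(.data$stimulus_label != "SHAM") |>
    dplyr::mutate(
      .stim_rank = match(.data$stimulus_label, bank_order),
      .cfg_rank = match(.data$configuration, gvs_configurations())
    )
  if (nrow(candidates) == 0) {
    stop("no non-sham conditions available for selection", call. = FALSE)
  }
  candidates |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$mean_err, .data$.stim_rank, .data$.cfg_rank,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "stimulus_label", "configuration",
                  "mean_err")
}

#' Performance improvement over sham
#'
#' Percentage improvement of a stimulus over sham,
#' \deqn{PI_{GVS} = 100 \times (ErrR_{SHAM} - ErrR_{GVS}) / ErrR_{GVS},}
#' where both errors are a participant's mean tracking errors (by default
#' averaged across the two electrode configurations). Positive values mean
#' the stimulus lowered tracking error relative to sham.
#'
#' @param err_sham,err_gvs mean tracking errors in screen units
#'   (`err_gvs > 0`).
#' @return Percentage improvement.
#' @examples
#' pi_over_sham(1.25, 1)  # 25
#' @export
pi_over_sham <- function(err_sham, err_gvs) {
  stopifnot(is.numeric(err_sham), is.numeric(err_gvs),
            length(err_sham) == length(err_gvs))
  if (any(err_gvs <= 0)) stop("`err_gvs` must be positive", call. = FALSE)
  100 * (err_sham - err_gvs) / err_gvs
}

#' Performance improvement of the individualised stimulus
#'
#' Percentage improvement of a participant's individualised stimulus over
#' another stimulus,
#' \deqn{PI_{Ind} = 100 \times (ErrR_{GVS} - ErrR_{Ind}) / ErrR_{Ind}.}
#' By convention `err_ind` is the error of the individualised
#' (stimulus, configuration) cell itself, while `err_gvs` is the comparison
#' stimulus's error averaged across configurations.
#'
#' @param err_gvs comparison-stimulus mean error.
#' @param err_ind individualised-stimulus mean error (> 0).
#' @return Percentage improvement.
#' @examples
#' pi_individualised(1.24, 1)  # 24
#' @export
pi_individualised <- function(err_gvs, err_ind) {
  stopifnot(is.numeric(err_gvs), is.numeric(err_ind),
            length(err_gvs) == length(err_ind))
  if (any(err_ind <= 0)) stop("`err_ind` must be positive", call. = FALSE)
  100 * (err_gvs - err_ind) / err_ind
}

#' Per-stimulus improvement report
#'
#' Builds the cohort-level improvement table: for every bank stimulus (and
#' sham), the mean across participants of (a) the improvement of the
#' participant's individualised stimulus over that stimulus and (b) the
#' improvement of that stimulus over sham. Per-participant errors enter
#' averaged across the two configurations, except the individualised error,
#' which by default is the selected cell's own (single-configuration) error;
#' `individualised = "cross_config"` switches to the cross-configuration
#' average of the selected stimulus.
#'
#' The SHAM row reads as: improvement of individualised stimulation over
#' sham, and 0 (sham against itself).
#'
#' @inheritParams metrics_table
#' @param individualised `"min_cell"` (default) or `"cross_config"`.
#' @return A tibble with columns `stimulus_label`,
#'   `improvement_individualised_pct`, `improvement_over_sham_pct`.
#' @export
improvement_table <- function(subtrials,
                              individualised = c("min_cell", "cross_config")) {
  individualised <- match.arg(individualised)
  per_cond <- metrics_table(subtrials)
  cross <- cross_config_means(subtrials)
  if (any(per_cond$stimulus_label != "SHAM")) {
    choice <- select_individualised(per_cond)
    if (individualised == "cross_config") {
      choice <- choice |>
        dplyr::select(-"mean_err") |>
        dplyr::left_join(cross, by = c("participant_id", "stimulus_label"))
    }
    err_ind <- choice |>
      dplyr::select("participant_id", err_ind = "mean_err")
  } else {
    err_ind <- tibble::tibble(participant_id = unique(per_cond$participant_id),
                              err_ind = NA_real_)
  }
  sham <- cross |>
    dplyr::filter(.data$stimulus_label == "SHAM") |>
    dplyr::select("participant_id", err_sham = "mean_err")
  per_part <- cross |>
    dplyr::left_join(err_ind, by = "participant_id") |>
    dplyr::left_join(sham, by = "participant_id") |>
    dplyr::mutate(
      pi_ind = dplyr::if_else(
        is.na(.data$err_ind), NA_real_,
        100 * (.data$mean_err - .data$err_ind) / .data$err_ind
      ),
      pi_gvs = pi_over_sham(.data$err_sham, .data$mean_err)
    )
  order_labels <- c(names(.gvs_bank_freqs), "SHAM")
  per_part |>
    dplyr::group_by(.data$stimulus_label) |>
    dplyr::summarise(
      improvement_individualised_pct = mean(.data$pi_ind),
      improvement_over_sham_pct = mean(.data$pi_gvs),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$stimulus_label, order_labels))
}
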