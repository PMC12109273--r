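# Statistical layer: mixed-effects configuration contrast, paired Wilcoxon
# signed-rank test, and Benjamini-Hochberg FDR adjustment.

new_test_result <- function(test_name, scope, estimate, p_value,
                            p_adjusted = NA_real_) {
  tibble::tibble(test_name = test_name, scope = scope,
                 estimate = estimate, p_value = p_value,
                 p_adjusted = p_adjusted)
}

#' Mixed-effects contrast of electrode configurations
#'
#' Tests for a difference in sub-trial mean tracking error between the
#' two-pole and three-pole configurations with a linear mixed-effects model.
#' Sub-trials within a trial are not independent, so the model is
#' `mean_err ~ configuration` with crossed random intercepts for participant
#' and for sub-trial index; estimation is by REML (via \pkg{lme4}) and the
#' fixed-effect p-value comes from the large-sample normal approximation of
#' the coefficient. A positive estimate means the three-pole configuration
#' had larger error than the two-pole baseline.
#'
#' When the scope contains a single participant (per-participant analyses)
#' the participant random effect is dropped and only the sub-trial intercept
#' remains. A singular fit triggers a fallback to the
#' participant-intercept-only model with a warning.
#'
#' @param table long tibble with columns `participant_id`, `configuration`,
#'   `stimulus_label`, `subtrial_index`, `mean_err`.
#' @param scope `"all"` (every stimulus pooled) or one stimulus label, e.g.
#'   `"GVS8"`.
#' @return A one-row tibble: `test_name`, `scope`, `estimate` (three-pole
#'   minus two-pole, screen units), `p_value`, `p_adjusted` (NA here; filled
#'   by [bh_fdr()] across a family).
#' @export
lme_config_contrast <- function(table, scope = "all") {
  needed <- c("participant_id", "configuration", "stimulus_label",
              "subtrial_index", "mean_err")
  stopifnot(all(needed %in% names(table)))
  if (!identical(scope, "all")) {
    table <- table[table$stimulus_label == scope, ]
    if (nrow(table) == 0) stop("no rows for stimulus ", scope, call. = FALSE)
  }
  if (length(unique(table$configuration)) < 2) {
    stop("both electrode configurations must be present in scope",
         call. = FALSE)
  }
  table$configuration <- factor(table$configuration,
                                levels = gvs_configurations())
  n_participants <- length(unique(table$participant_id))
  formula <- if (n_participants >= 2) {
    mean_err ~ configuration + (1 | participant_id) + (1 | subtrial_index)
  } else {
    mean_err ~ configuration + (1 | subtrial_index)
  }
  fit <- suppressMessages(lme4::lmer(formula, data = table, REML = TRUE))
  if (lme4::isSingular(fit) && n_participants >= 2) {
    warning("singular mixed-model fit; falling back to participant-only random intercept",
            call. = FALSE)
    fit <- suppressMessages(
      lme4::lmer(mean_err ~ configuration + (1 | participant_id), data = table,
                 REML = TRUE)
    )
  }
  coefs <- summary(fit)$coefficients
  est <- coefs["configurationthree_pole", "Estimate"]
  z <- coefs["configurationthree_pole", "t value"]
  new_test_result("lme_config_contrast", scope,
                  estimate = unname(est),
                  p_value = 2 * stats::pnorm(-abs(z)))
}

#' Per-stimulus configuration contrasts with FDR control
#'
#' Runs [lme_config_contrast()] for each non-sham stimulus and adjusts the
#' family of p-values with [bh_fdr()].
#'
#' @inheritParams lme_config_contrast
#' @return A tibble with one row per stimulus.
#' @export
lme_config_contrast_by_stimulus <- function(table) {
  labels <- setdiff(unique(table$stimulus_label), "SHAM")
  res <- dplyr::bind_rows(lapply(labels, function(s) {
    lme_config_contrast(table, scope = s)
  }))
  res$p_adjusted <- bh_fdr(res$p_value)
  res
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test of per-participant mean errors, used
#' for sham versus individualised stimulation. Zero differences are dropped;
#' the exact null distribution is used for up to 25 non-zero pairs (ties
#' permitting), the normal approximation with continuity correction
#' otherwise. The estimate reported is the median paired difference
#' (`ind - sham`; negative means individualised stimulation lowered error).
#'
#' @param sham_means,ind_means numeric vectors of per-participant mean
#'   errors, paired by position, length >= 5.
#' @return A one-row result tibble as in [lme_config_contrast()].
#' @examples
#' wilcoxon_paired(c(5, 6, 7, 8, 9), c(4, 5, 6, 7, 8))
#' @export
wilcoxon_paired <- function(sham_means, ind_means) {
  stopifnot(is.numeric(sham_means), is.numeric(ind_means))
  if (length(sham_means) != length(ind_means) || length(sham_means) < 5) {
    stop("inputs must be paired vectors of length >= 5", call. = FALSE)
  }
  d <- ind_means - sham_means
  nonzero <- d[d != 0]
  if (length(nonzero) == 0) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(new_test_result("wilcoxon_signed_rank", "sham_vs_individualised",
                           estimate = 0, p_value = 1))
  }
  exact <- length(nonzero) <= 25
  ht <- suppressWarnings(
    stats::wilcox.test(ind_means, sham_means, paired = TRUE,
                       exact = exact, correct = TRUE)
  )
  new_test_result("wilcoxon_signed_rank", "sham_vs_individualised",
                  estimate = stats::median(d), p_value = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate:
#' after sorting ascending, `q(i) = min_{j >= i} m p(j) / j`, mapped back to
#' the input order and capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("`p_values` must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Bootstrap standard error of the median
#'
#' Seeded nonparametric bootstrap of the median, used for error bars on
#' pooled median tracking error.
#'
#' @param x numeric vector.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return Standard deviation of the bootstrap medians.
#' @export
median_se_bootstrap <- function(x, n_resamples = 1000, seed = 1L) {
  stopifnot(is.numeric(x), length(x) >= 2, n_resamples >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  meds <- replicate(n_resamples, stats::median(sample(x, replace = TRUE)))
  stats::sd(meds)
}
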