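# broom-style tidiers for the battery and result objects.

#' Tidy a statistical battery
#'
#' One row per (texture map, statistic, interval, tissue pair) with the raw
#' and adjusted p-value and the significance call.
#'
#' @param x A `dtpa_battery` from [run_full_battery()].
#' @param ... Unused.
#' @return A tibble with columns `tpm_type`, `statistic`, `interval`,
#'   `anova_p`, `gated`, `pair`, `p_raw`, `p_adj`, `significant`.
#' @export
tidy.dtpa_battery <- function(x, ...) {
  alpha <- attr(x, "alpha")
  long_p <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("tpm_type", "statistic", "interval", "anova_p",
                             "gated", paste0("p_", TISSUE_PAIRS))],
    cols = dplyr::starts_with("p_"), names_to = "pair", values_to = "p_raw",
    names_prefix = "p_")
  long_q <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("tpm_type", "statistic", "interval",
                             paste0("q_", TISSUE_PAIRS))],
    cols = dplyr::starts_with("q_"), names_to = "pair", values_to = "p_adj",
    names_prefix = "q_")
  out <- dplyr::left_join(long_p, long_q,
                          by = c("tpm_type", "statistic", "interval", "pair"))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Battery one-line summary
#'
#' @param x A `dtpa_battery`.
#' @param ... Unused.
#' @return A one-row tibble: number of cells, gated cells, performed and
#'   significant pairwise tests, possible tests and the expected
#'   false-positive count at the battery's alpha.
#' @export
glance.dtpa_battery <- function(x, ...) {
  alpha <- attr(x, "alpha")
  qcols <- paste0("q_", TISSUE_PAIRS)
  Q <- as.matrix(x[, qcols])
  tibble::tibble(
    n_cells = nrow(x),
    n_gated = sum(x$gated, na.rm = TRUE),
    n_tests_performed = sum(!is.na(Q)),
    n_significant = sum(Q < alpha, na.rm = TRUE),
    n_tests_possible = 3L * nrow(x),
    alpha = alpha,
    expected_false_positives = 3L * nrow(x) * alpha)
}

#' @export
tidy.dtpa_result <- function(x, ...) x$records

#' @export
glance.dtpa_result <- function(x, ...) {
  base <- tibble::tibble(
    n_records = nrow(x$records),
    n_tois = length(unique(x$records$toi_label)),
    toa = x$phases$toa, t_peak = x$phases$t_peak, t_min = x$phases$t_min,
    coil_factor = x$normalization$coil_factor,
    auc_factor = x$normalization$auc_factor)
  if (!is.null(x$tests)) dplyr::bind_cols(base, glance(x$tests)) else base
}
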