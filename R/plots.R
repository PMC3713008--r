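# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a concentration curve with optional phase shading
#'
#' @param object A `concentration_curve`.
#' @param phases Optional [bolus_phases] to shade the four intervals.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concentration_curve <- function(object, phases = NULL, ...) {
  df <- tibble::tibble(time = seq_along(object$values), value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (!is.null(phases)) {
    bands <- tibble::tibble(
      interval = factor(INTERVALS, levels = INTERVALS),
      xmin = c(phases$t_first - 0.5, phases$toa - 0.5, phases$t_peak + 0.5,
               phases$t_min + 0.5),
      xmax = c(phases$toa - 0.5, phases$t_peak + 0.5, phases$t_min + 0.5,
               phases$t_end + 0.5))
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$interval),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time index", y = "relative concentration",
                  title = sprintf("Bolus passage, region '%s'", object$region_label),
                  fill = "interval") +
    ggplot2::theme_minimal()
}

#' Plot one slice of a texture parameter map
#'
#' @param object A `tpm_series`.
#' @param time Time index to display.
#' @param slice Slice index.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.tpm_series <- function(object, time = 1L, slice = 1L, ...) {
  d <- dim(object$values)
  img <- matrix(object$values[time, slice, , ], d[3], d[4])
  df <- tidyr::expand_grid(row = seq_len(d[3]), col = seq_len(d[4]))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("TPM-%s, t = %d, slice %d",
                                  object$tpm_type, time, slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Interval-averaged TOI statistics by tissue class
#'
#' Displays the mean (with one standard deviation across regions) of one
#' statistic per texture map, interval and tissue class — the record-level
#' view underlying the battery.
#'
#' @param records Record tibble from [extract_toi_records()].
#' @param statistic Which of the six statistics to display.
#' @return A ggplot.
#' @export
plot_interval_profiles <- function(records, statistic = "mean") {
  stat <- match.arg(statistic, TOI_STATISTICS)
  df <- records |>
    dplyr::filter(.data$statistic == stat, !.data$undetermined) |>
    dplyr::group_by(.data$tpm_type, .data$interval, .data$tissue_class) |>
    dplyr::summarise(m = mean(.data$value), s = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$m,
                                   colour = .data$tissue_class,
                                   group = .data$tissue_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$s,
                                          ymax = .data$m + .data$s),
                             size = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tpm_type), scales = "free_y") +
    ggplot2::labs(x = NULL, y = sprintf("TOI %s (interval average)", stat),
                  colour = "tissue") +
    ggplot2::theme_minimal()
}
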