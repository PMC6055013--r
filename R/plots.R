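#' Scatter plot of one indicator against another
#'
#' Per-measure scatter coloured by sector, by default on log-log axes —
#' the natural scale for indicators spanning several orders of magnitude.
#'
#' @param indicators Indicator table from [compute_indicators()], or any
#'   data frame of per-measure values with a `sector` column.
#' @param x,y Columns to plot (tidy evaluation).
#' @param log Use log10 axes? Default `TRUE` (non-positive values are
#'   dropped by the scale).
#' @return A ggplot object.
#' @export
plot_indicator_scatter <- function(indicators, x = ccb, y = aqb_pm25,
                                   log = TRUE) {
  xq <- enquo(x); yq <- enquo(y)
  p <- ggplot2::ggplot(indicators,
                       ggplot2::aes(x = !!xq, y = !!yq,
                                    colour = .data$sector)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(colour = "Sector") +
    ggplot2::theme_minimal()
  if (log) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Boxplot of a per-measure quantity by sector
#'
#' @param data Data frame with a `sector` column (e.g. the measures table
#'   or an indicator table).
#' @param value Column to plot (tidy evaluation).
#' @param log Use a log10 value axis? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_sector_boxplot <- function(data, value, log = TRUE) {
  vq <- enquo(value)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = factor(.data$sector, levels = SECTORS),
                                    y = !!vq, fill = .data$sector)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "Sector") +
    ggplot2::theme_minimal()
  if (log) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn fit_through_origin Scatter of the fitted data with the
#'   through-origin line and its confidence band.
#' @param object An `origin_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.origin_fit <- function(object, ...) {
  d <- tibble::tibble(x = object$x, y = object$y)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(intercept = 0, slope = object$alpha,
                         colour = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(subtitle = sprintf("alpha = %.4g, R^2 = %.2f, n = %d",
                                     object$alpha, object$r_squared,
                                     object$n))
  if (!object$degenerate && all(is.finite(object$ci))) {
    p <- p +
      ggplot2::geom_abline(intercept = 0, slope = object$ci[1],
                           colour = "steelblue", linetype = "dashed") +
      ggplot2::geom_abline(intercept = 0, slope = object$ci[2],
                           colour = "steelblue", linetype = "dashed")
  }
  p
}

#' Health-benefit totals per sector with confidence bounds
#'
#' Bar chart of aggregated avoided premature deaths or years of life
#' saved per sector, with the (low, high) bound interval.
#'
#' @param health Sector health table from [aggregate_health()] with
#'   `by = "sector"`.
#' @param what `"pd"` (premature deaths, default) or `"yls"`.
#' @return A ggplot object.
#' @export
plot_health_totals <- function(health, what = c("pd", "yls")) {
  what <- match.arg(what)
  d <- health[health$group != "Total", ]
  cols <- paste0(what, c("_central", "_low", "_high"))
  d <- tibble::tibble(group = d$group, central = d[[cols[1]]],
                      low = d[[cols[2]]], high = d[[cols[3]]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$central)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                           width = 0.2) +
    ggplot2::labs(x = NULL,
                  y = if (what == "pd") "Avoided premature deaths / y"
                      else "Years of life saved / y") +
    ggplot2::theme_minimal()
}
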