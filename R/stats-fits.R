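#' Regression through the origin
#'
#' Fits the no-intercept linear model `y = alpha * x` by least squares:
#' `alpha = sum(x*y) / sum(x^2)`, with a t-based confidence interval on
#' `n - 1` degrees of freedom (standard error `sqrt(RSS / (n-1) /
#' sum(x^2))`) and the uncentered coefficient of determination `R^2 = 1 -
#' RSS / sum(y^2)` — the convention under which a through-origin R-squared
#' is guaranteed to lie in `[0, 1]`. A single observation yields the exact
#' slope with a degenerate (undefined) interval.
#'
#' @param x,y Numeric vectors of equal length (`n >= 1`); `sum(x^2)` must
#'   be positive.
#' @param conf_level Confidence level for the slope interval (default
#'   0.95).
#' @return An object of class `origin_fit` with elements `alpha`,
#'   `ci` (length-2), `se`, `r_squared`, `n`, `df`, `conf_level`,
#'   `degenerate`, and the data (`x`, `y`) for plotting. Supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#' @examples
#' fit_through_origin(c(1, 2, 3), c(2, 4.1, 5.9))
#' @export
fit_through_origin <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 1) abort("Need at least one complete observation.")
  sxx <- sum(x^2)
  if (sxx <= 0) abort("Degenerate fit: all x are zero.")
  alpha <- sum(x * y) / sxx
  rss <- sum((y - alpha * x)^2)
  syy <- sum(y^2)
  r_squared <- if (syy > 0) 1 - rss / syy else 1
  # numerical guard: rss can exceed syy only through rounding
  r_squared <- min(max(r_squared, 0), 1)
  degenerate <- n < 2
  if (!degenerate) {
    se <- sqrt(rss / (n - 1) / sxx)
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- c(alpha - tq * se, alpha + tq * se)
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(alpha = alpha, ci = ci, se = se, r_squared = r_squared,
                 n = n, df = n - 1L, conf_level = conf_level,
                 degenerate = degenerate, x = x, y = y),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat("Through-origin fit  y = alpha * x\n")
  cat(sprintf("  alpha = %.6g", x$alpha))
  if (!x$degenerate) {
    cat(sprintf("  [%.6g, %.6g] (%g%% CI)", x$ci[1], x$ci[2],
                100 * x$conf_level))
  } else {
    cat("  (degenerate: single observation, no interval)")
  }
  cat(sprintf("\n  R^2 (uncentered) = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.origin_fit <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha, std.error = x$se,
                 statistic = if (!x$degenerate && x$se > 0) x$alpha / x$se
                             else NA_real_,
                 conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @exportS3Method generics::glance
glance.origin_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n, df.residual = x$df,
                 conf.level = x$conf_level, degenerate = x$degenerate)
}

#' Through-origin fits per sector and pooled
#'
#' Fits `y = alpha * x` (see [fit_through_origin()]) on the pooled sample
#' (`group = "All"`) and within each sector. Sectors whose uncentered
#' R-squared falls below `min_r2` are flagged, not dropped; sectors with
#' fewer than two complete observations are flagged degenerate.
#'
#' @param data Data frame of per-measure values, e.g. the indicator table
#'   from [compute_indicators()].
#' @param x,y Columns to fit (tidy evaluation), e.g. `ccb` and `aqb_pm25`.
#' @param by Grouping column (default `sector`).
#' @param min_r2 R-squared threshold below which a group's fit is flagged
#'   (default 0.4).
#' @param conf_level Confidence level for slope intervals.
#' @return A tibble with one row per group plus the pooled row: `group`,
#'   `n`, `alpha`, `ci_low`, `ci_high`, `se`, `r_squared`, `low_r2`,
#'   `degenerate`.
#' @export
sectorwise_fits <- function(data, x, y, by = sector, min_r2 = 0.4,
                            conf_level = 0.95) {
  xq <- enquo(x); yq <- enquo(y); byq <- enquo(by)
  d <- dplyr::transmute(data, g = as.character(!!byq), x = !!xq, y = !!yq)
  fit_row <- function(dd, label) {
    dd <- dd[!is.na(dd$x) & !is.na(dd$y), ]
    if (nrow(dd) < 2) {
      f <- if (nrow(dd) == 1) fit_through_origin(dd$x, dd$y, conf_level) else NULL
      return(tibble::tibble(group = label, n = nrow(dd),
                            alpha = if (is.null(f)) NA_real_ else f$alpha,
                            ci_low = NA_real_, ci_high = NA_real_,
                            se = NA_real_,
                            r_squared = NA_real_, low_r2 = NA,
                            degenerate = TRUE))
    }
    f <- fit_through_origin(dd$x, dd$y, conf_level)
    tibble::tibble(group = label, n = f$n, alpha = f$alpha,
                   ci_low = f$ci[1], ci_high = f$ci[2], se = f$se,
                   r_squared = f$r_squared,
                   low_r2 = f$r_squared < min_r2, degenerate = FALSE)
  }
  groups <- unique(d$g)
  groups <- c(intersect(SECTORS, groups), setdiff(sort(groups), SECTORS))
  dplyr::bind_rows(
    fit_row(d, "All"),
    purrr::map_dfr(groups, function(g) fit_row(d[d$g == g, ], g))
  )
}
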