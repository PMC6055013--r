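#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test,
#' between/within decomposition) of a value column across a grouping
#' column, computed with [stats::oneway.test()]. Groups with fewer than
#' two observations are dropped with a warning; fewer than two remaining
#' groups is an error. With `log10_transform = TRUE` the test is applied
#' to `log10(value)` after discarding non-positive values — appropriate
#' for quantities spanning several orders of magnitude, such as per-measure
#' CO2 reductions.
#'
#' @param data Data frame.
#' @param value Value column (tidy evaluation).
#' @param group Grouping column (tidy evaluation).
#' @param log10_transform Test on the log10 scale? Default `FALSE`.
#' @return An object of class `cobenefit_anova` with elements `f_stat`,
#'   `p_value`, `df_between`, `df_within`, `group_sizes`, `log10_transform`.
#'   Supports [tidy()], [glance()] and `print()`.
#' @examples
#' one_way_anova(data.frame(v = c(1, 2, 3, 2, 3, 4),
#'                          g = rep(c("A", "B"), each = 3)), v, g)
#' @export
one_way_anova <- function(data, value, group, log10_transform = FALSE) {
  vq <- enquo(value); gq <- enquo(group)
  d <- dplyr::transmute(data, v = !!vq, g = as.character(!!gq))
  d <- d[!is.na(d$v) & !is.na(d$g), ]
  if (isTRUE(log10_transform)) {
    n_pos <- sum(d$v > 0)
    if (n_pos < nrow(d)) {
      warn(sprintf("%d non-positive value(s) dropped before log10 transform",
                   nrow(d) - n_pos))
    }
    d <- d[d$v > 0, ]
    d$v <- log10(d$v)
  }
  sizes <- table(d$g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(sprintf("Dropping group(s) with fewer than 2 values: %s",
                 paste(small, collapse = ", ")))
    d <- d[!d$g %in% small, ]
    sizes <- table(d$g)
  }
  if (length(sizes) < 2) abort("Need at least two groups with >= 2 values each.")
  ot <- stats::oneway.test(v ~ g, data = d, var.equal = TRUE)
  structure(list(f_stat = unname(ot$statistic),
                 p_value = unname(ot$p.value),
                 df_between = as.integer(unname(ot$parameter[1])),
                 df_within = as.integer(unname(ot$parameter[2])),
                 group_sizes = setNames(as.integer(sizes), names(sizes)),
                 log10_transform = isTRUE(log10_transform)),
            class = "cobenefit_anova")
}

#' @export
print.cobenefit_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F(%d, %d) = %.4g, p = %.4g\n",
              if (x$log10_transform) " (log10 scale)" else "",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  cat("  group sizes:",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cobenefit_anova <- function(x, ...) {
  tibble::tibble(term = "group", statistic = x$f_stat, p.value = x$p_value,
                 df = x$df_between, df.residual = x$df_within)
}

#' @exportS3Method generics::glance
glance.cobenefit_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f_stat, p.value = x$p_value,
                 df = x$df_between, df.residual = x$df_within,
                 n.groups = length(x$group_sizes),
                 nobs = sum(x$group_sizes),
                 log10 = x$log10_transform)
}
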