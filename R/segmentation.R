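#' Segment measures by a city-level variable
#'
#' Splits the measures into two groups by their city's population or
#' pollution level. A numeric `rule` is a threshold: cities strictly above
#' it take the first label, cities at or below it the second (a city
#' exactly at the threshold goes below). `rule = "median"` computes the
#' median over distinct cities (not over measures) and assigns strictly
#' above-median cities to the first label, ties to the second.
#'
#' @param x A `cobenefit_data` object.
#' @param variable `"population"`, `"pm25"` or `"nox"`.
#' @param rule Numeric threshold or `"median"` (default).
#' @param labels Character pair `(above, below)`.
#' @return `x` with a `segment` column added to `$cities` and `$measures`;
#'   the threshold used is stored in `attr(, "segment_threshold")`. Use
#'   [split_segments()] for one sub-dataset per label.
#' @examples
#' \dontrun{
#' seg <- segment_measures(d, "population", 2e5, c("large", "small"))
#' split_segments(seg)
#' }
#' @export
segment_measures <- function(x, variable = c("population", "pm25", "nox"),
                             rule = "median", labels = c("High", "Low")) {
  stopifnot(inherits(x, "cobenefit_data"), length(labels) == 2)
  variable <- match.arg(variable)
  v <- x$cities[[variable]]
  if (identical(rule, "median")) {
    threshold <- median(v)
  } else if (is.numeric(rule) && length(rule) == 1 && rule > 0) {
    threshold <- rule
  } else {
    abort('`rule` must be "median" or a single positive number.')
  }
  x$cities$segment <- ifelse(v > threshold, labels[1], labels[2])
  x$measures$segment <- NULL
  x$measures <- dplyr::left_join(
    x$measures, dplyr::select(x$cities, "city_id", "segment"), by = "city_id")
  x$provenance <- add_provenance(
    x$provenance, "segmentation",
    sprintf("cities segmented by %s at %.6g", variable, threshold),
    nrow(x$cities), paste(labels, collapse = "/"))
  attr(x, "segment_threshold") <- threshold
  x
}

#' @rdname segment_measures
#' @return For `split_segments()`: a named list of `cobenefit_data`
#'   objects, one per segment label, each restricted to that segment's
#'   cities and their measures.
#' @export
split_segments <- function(x) {
  stopifnot(inherits(x, "cobenefit_data"))
  if (is.null(x$cities$segment)) abort("Run `segment_measures()` first.")
  labs <- unique(x$cities$segment)
  out <- lapply(labs, function(l) {
    y <- x
    y$cities <- dplyr::filter(y$cities, .data$segment == l)
    y$measures <- dplyr::semi_join(y$measures, y$cities, by = "city_id")
    y$sector_energy <- dplyr::semi_join(y$sector_energy, y$cities, by = "city_id")
    y$sce <- dplyr::semi_join(y$sce, y$cities, by = "city_id")
    y
  })
  setNames(out, labs)
}

#' Mean absolute and per-capita CO2 reduction per measure
#'
#' For each group of measures (all, or a segmentation label), the
#' unweighted mean over measures of the absolute CO2 reduction and of the
#' per-capita reduction (each measure's CO2 reduction divided by its own
#' city's population).
#'
#' @param x A `cobenefit_data` object, segmented with [segment_measures()]
#'   if per-group rows are wanted.
#' @param by `"segment"` (default, requires a prior segmentation) or
#'   `"all"`.
#' @return A tibble with columns `group`, `n_measures`, `mean_co2_t`,
#'   `mean_co2_per_capita`.
#' @export
per_capita_summary <- function(x, by = c("segment", "all")) {
  stopifnot(inherits(x, "cobenefit_data"))
  by <- match.arg(by)
  d <- dplyr::inner_join(
    x$measures, dplyr::select(x$cities, "city_id", "population"),
    by = "city_id")
  d$group <- if (by == "segment") {
    if (is.null(d$segment)) abort("Run `segment_measures()` first.")
    d$segment
  } else "all"
  d |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(n_measures = dplyr::n(),
                     mean_co2_t = mean(.data$co2_reduction %na0% 0),
                     mean_co2_per_capita =
                       mean((.data$co2_reduction %na0% 0) / .data$population),
                     .groups = "drop")
}

#' Aggregate health benefits, bound by bound
#'
#' Sums the city-total avoided premature deaths and years of life saved
#' over measures, keeping the (low, central, high) bounds separate
#' (bound-by-bound summation). With `by = "sector"` one row per sector is
#' returned plus a `Total` row that equals the column sums exactly.
#'
#' @param indicators Indicator table from [compute_indicators()].
#' @param by `"all"` or `"sector"`.
#' @return A tibble with columns `group`, `n_measures`, `pd_low`,
#'   `pd_central`, `pd_high`, `yls_low`, `yls_central`, `yls_high`.
#' @export
aggregate_health <- function(indicators, by = c("all", "sector")) {
  by <- match.arg(by)
  cols <- c("pd_low", "pd_central", "pd_high",
            "yls_low", "yls_central", "yls_high")
  sum_rows <- function(d, label) {
    tibble::as_tibble(c(list(group = label, n_measures = nrow(d)),
                        lapply(setNames(cols, cols),
                               function(cc) sum(d[[cc]]))))
  }
  if (by == "all" || nrow(indicators) == 0) {
    return(sum_rows(indicators, "All"))
  }
  secs <- intersect(SECTORS, unique(indicators$sector))
  dplyr::bind_rows(
    purrr::map_dfr(secs, function(s) {
      sum_rows(indicators[indicators$sector == s, ], s)
    }),
    sum_rows(indicators, "Total")
  )
}
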