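#' Classify mitigation measures as ES, REP, MIX or UNCLASSIFIED
#'
#' A measure is an Energy Saving (ES) measure when it reports a positive
#' energy saving and no renewable production, a Renewable Energy Production
#' (REP) measure in the opposite case, MIX when both are positive, and
#' UNCLASSIFIED when both fields are zero or missing (zero and missing are
#' treated identically: no reported effort).
#'
#' @param x A `cobenefit_data` object.
#' @return `x` with the `category` column of `$measures` filled in.
#' @export
classify_measures <- function(x) {
  stopifnot(inherits(x, "cobenefit_data"))
  x$measures$category <- classify_category(x$measures$energy_saved,
                                           x$measures$renewable)
  x$provenance <- add_provenance(
    x$provenance, "classification", "measures classified", nrow(x$measures),
    paste(names(table(x$measures$category)), table(x$measures$category),
          sep = "=", collapse = ", "))
  x
}

#' @rdname classify_measures
#' @param energy_saved,renewable Numeric vectors (MWh/y); `NA` means
#'   missing.
#' @return For `classify_category()`: a character vector of categories.
#' @examples
#' classify_category(c(500, 0, 0, 10), c(NA, 200, NA, 5))
#' @export
classify_category <- function(energy_saved, renewable) {
  if (any(energy_saved < 0, na.rm = TRUE) || any(renewable < 0, na.rm = TRUE)) {
    abort("energy fields must be non-negative or missing")
  }
  es <- !is.na(energy_saved) & energy_saved > 0
  rep_ <- !is.na(renewable) & renewable > 0
  dplyr::case_when(es & !rep_ ~ "ES",
                   rep_ & !es ~ "REP",
                   es & rep_ ~ "MIX",
                   .default = "UNCLASSIFIED")
}

#' Restrict a dataset to plausible Energy Saving measures
#'
#' Keeps only ES measures and applies the consumption-exceedance exclusion
#' rule: an ES measure claiming to save strictly more energy than its city
#' consumes in the target sector is excluded (a saving equal to the whole
#' sector consumption is kept). ES measures whose sector has no inventory
#' record in their city are also excluded, logged separately. The
#' classification report is attached and retrievable with
#' [classification_report()].
#'
#' @param x A `cobenefit_data` object; classified with
#'   [classify_measures()] first if needed.
#' @return `x` with `$measures` reduced to the retained ES measures and a
#'   report attached.
#' @export
filter_es <- function(x) {
  stopifnot(inherits(x, "cobenefit_data"))
  if (all(is.na(x$measures$category))) x <- classify_measures(x)
  counts <- table(factor(x$measures$category, levels = CATEGORIES))
  counts_by_category <- setNames(as.integer(counts), CATEGORIES)

  es <- dplyr::filter(x$measures, .data$category == "ES") |>
    dplyr::left_join(x$sector_energy, by = c("city_id", "sector"))
  no_sector <- is.na(es$energy_mwh)
  exceeds <- !no_sector & es$energy_saved > es$energy_mwh
  kept <- es[!no_sector & !exceeds, ] |> dplyr::select(-"energy_mwh")

  report <- list(
    counts_by_category = counts_by_category,
    excluded_count = as.integer(sum(no_sector) + sum(exceeds)),
    excluded_exceedance = as.integer(sum(exceeds)),
    excluded_no_sector_energy = as.integer(sum(no_sector)),
    final_es_count = nrow(kept)
  )
  x$measures <- kept
  x$provenance <- add_provenance(
    x$provenance, "filter_es", "ES measures exceeding sector consumption excluded",
    report$excluded_exceedance, "energy_saved > sector energy")
  if (report$excluded_no_sector_energy > 0) {
    x$provenance <- add_provenance(
      x$provenance, "filter_es", "ES measures without sector inventory excluded",
      report$excluded_no_sector_energy, "sector absent from city BEI")
  }
  attr(x, "es_report") <- report
  x
}

#' @rdname filter_es
#' @return For `classification_report()`: the list attached by
#'   `filter_es()` with elements `counts_by_category`, `excluded_count`
#'   (split into `excluded_exceedance` and `excluded_no_sector_energy`) and
#'   `final_es_count`.
#' @export
classification_report <- function(x) {
  rep <- attr(x, "es_report", exact = TRUE)
  if (is.null(rep)) abort("No report attached; run `filter_es()` first.")
  rep
}

#' Country-level summary of retained Energy Saving measures
#'
#' One row per country with the number of signatory cities, their combined
#' population, the number of ES measures and their cumulative energy saved
#' (TWh/y) and CO2 reduction (MtCO2-eq/y), closed by a `Total` row equal to
#' the column sums. Signatories and population count the distinct cities
#' that implement at least one retained measure.
#'
#' @param x A `cobenefit_data` object, normally after [filter_es()].
#' @param total Append the `Total` row? Default `TRUE`.
#' @return A tibble with columns `country`, `n_signatories`, `population`,
#'   `n_es_measures`, `energy_saved_twh`, `co2_reduction_mt`.
#' @export
summarize_by_country <- function(x, total = TRUE) {
  stopifnot(inherits(x, "cobenefit_data"))
  per_city <- x$measures |>
    dplyr::group_by(.data$city_id) |>
    dplyr::summarise(n_measures = dplyr::n(),
                     energy = sum(.data$energy_saved %na0% 0),
                     co2 = sum(.data$co2_reduction %na0% 0),
                     .groups = "drop") |>
    dplyr::inner_join(x$cities, by = "city_id")
  out <- per_city |>
    dplyr::group_by(country = .data$country) |>
    dplyr::summarise(n_signatories = dplyr::n(),
                     population = sum(.data$population),
                     n_es_measures = sum(.data$n_measures),
                     energy_saved_twh = sum(.data$energy) * 1e-6,
                     co2_reduction_mt = sum(.data$co2) * 1e-6,
                     .groups = "drop") |>
    dplyr::arrange(.data$country)
  if (total) out <- add_total_row(out)
  out
}

#' @rdname summarize_by_country
#' @param df A country summary tibble without a total row.
#' @return For `add_total_row()`: `df` with a final `Total` row whose every
#'   numeric field is the column sum.
#' @export
add_total_row <- function(df) {
  tot <- df |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum)) |>
    dplyr::mutate(country = "Total")
  dplyr::bind_rows(df, tot)
}

#' Sector-level measure counts and energy shares
#'
#' Tallies measures and energy saved per sector, with fractional shares and
#' an integer-percent rendering by largest-remainder apportionment (see
#' [integer_percent_shares()]). Works on whichever measure set the caller
#' supplies: the full classified set for overall shares, or the post-filter
#' ES set for ES shares.
#'
#' @param x A `cobenefit_data` object.
#' @return A tibble with one row per sector: `sector`, `n_measures`,
#'   `count_share`, `count_pct`, `energy_saved_mwh`, `energy_share`,
#'   `energy_pct`. Shares sum to 1, percents to 100.
#' @export
summarize_by_sector <- function(x) {
  stopifnot(inherits(x, "cobenefit_data"))
  out <- x$measures |>
    dplyr::mutate(sector = factor(.data$sector, levels = SECTORS)) |>
    dplyr::group_by(.data$sector, .drop = FALSE) |>
    dplyr::summarise(n_measures = dplyr::n(),
                     energy_saved_mwh = sum(.data$energy_saved %na0% 0),
                     .groups = "drop") |>
    dplyr::mutate(sector = as.character(.data$sector))
  n_tot <- sum(out$n_measures)
  e_tot <- sum(out$energy_saved_mwh)
  out$count_share <- if (n_tot > 0) out$n_measures / n_tot else 0
  out$energy_share <- if (e_tot > 0) out$energy_saved_mwh / e_tot else 0
  out$count_pct <- integer_percent_shares(out$n_measures)
  out$energy_pct <- integer_percent_shares(out$energy_saved_mwh)
  dplyr::select(out, "sector", "n_measures", "count_share", "count_pct",
                "energy_saved_mwh", "energy_share", "energy_pct")
}
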