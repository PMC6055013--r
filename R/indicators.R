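#' Climate Change Benefit of a measure
#'
#' CCB = EM_SAV / EM_TOT: the measure's CO2-equivalent emission reduction
#' as a fraction of the city's total baseline CO2 emissions. Like the AQB,
#' it quantifies impact on the share of emissions a local authority can
#' influence.
#'
#' @param em_sav CO2-equivalent emissions saved by the measure (t/y).
#' @param em_tot City total baseline CO2 emissions (t/y); must be > 0.
#' @return Dimensionless fraction (vectorized).
#' @examples
#' ccb(5000, 250000) # 0.02
#' @export
ccb <- function(em_sav, em_tot) {
  if (any(!is.na(em_tot) & em_tot <= 0)) {
    abort("Undefined indicator: city total CO2 must be > 0.")
  }
  em_sav / em_tot
}

#' Air Quality Benefit of an energy-saving measure
#'
#' AQB = (E_SAV / E_SEC) * (C_SEC / C_TOT): the fraction of the target
#' sector's energy consumption saved, weighted by that sector's share of
#' the four-sector urban contribution to the pollutant's urban-background
#' concentration. Intrinsically normalized to `[0, 1]` for measures that
#' survive the consumption-exceedance filter; AQB = 1 is the ideal measure
#' saving all energy in the sole polluting sector.
#'
#' @param e_sav Energy saved by the measure (MWh/y).
#' @param e_sec Energy consumption of the measure's sector in the city
#'   (MWh/y); must be > 0.
#' @param c_sec Contribution fraction of the sector's urban emissions to
#'   the pollutant's urban-background concentration.
#' @param c_tot Sum of the four sector contribution fractions; must be > 0.
#' @return Dimensionless fraction (vectorized).
#' @examples
#' aqb(100, 1000, 0.3, 0.5) # 0.06
#' @export
aqb <- function(e_sav, e_sec, c_sec, c_tot) {
  if (any(!is.na(e_sec) & e_sec <= 0)) {
    abort("Undefined indicator: sector energy consumption must be > 0.")
  }
  if (any(!is.na(c_tot) & c_tot <= 0)) {
    abort("Undefined indicator: total urban contribution must be > 0.")
  }
  (e_sav / e_sec) * (c_sec / c_tot)
}

#' Log-linear concentration-response relative risk for PM2.5
#'
#' RF = rr_per_10 ^ (pm25 / 10): the all-cause mortality relative risk at
#' an annual-mean PM2.5 concentration, from a log-linear
#' concentration-response function expressed as risk per 10 ug/m3. The
#' standard central estimate is 1.062 per 10 ug/m3 with 95% interval
#' (1.04, 1.083); see [rr_defaults()].
#'
#' @param pm25 Annual-mean PM2.5 concentration (ug/m3); must be >= 0.
#' @param rr_per_10 Relative risk per 10 ug/m3; must be > 0.
#' @return Dimensionless relative risk (vectorized).
#' @examples
#' relative_risk(10)        # 1.062
#' relative_risk(20, 1.062) # 1.062^2
#' @export
relative_risk <- function(pm25, rr_per_10 = 1.062) {
  if (any(!is.na(pm25) & pm25 < 0)) abort("PM2.5 concentration must be >= 0.")
  if (any(!is.na(rr_per_10) & rr_per_10 <= 0)) abort("rr_per_10 must be > 0.")
  rr_per_10^(pm25 / 10)
}

#' Attributable fraction of mortality
#'
#' AF = (RF - 1) / RF: the share of observed mortality attributable to the
#' exposure at relative risk RF. Strictly increasing in RF, 0 at RF = 1,
#' approaching 1 as RF grows.
#'
#' @param rf Relative risk; must be >= 1.
#' @return Fraction in `[0, 1)` (vectorized).
#' @examples
#' attributable_fraction(relative_risk(15))
#' @export
attributable_fraction <- function(rf) {
  if (any(!is.na(rf) & rf < 1)) abort("Relative risk must be >= 1.")
  (rf - 1) / rf
}

#' Default relative-risk bounds per 10 ug/m3 PM2.5
#'
#' Central estimate 1.062 with 95% confidence bounds 1.04 and 1.083; the
#' low/central/high triple is the only uncertainty source propagated
#' through the health chain.
#'
#' @return Named numeric vector `c(low, central, high)`.
#' @export
rr_defaults <- function() c(low = 1.04, central = 1.062, high = 1.083)

#' Avoided premature deaths per inhabitant for one exposure change
#'
#' The health-impact chain: `delta_pm25 * death_rate * frac_over_30 * AF`,
#' where `delta_pm25 = AQB * C_TOT * PM2.5` is the concentration decrease
#' attributable to the measure and AF is evaluated at the city's total
#' PM2.5 level via [relative_risk()] and [attributable_fraction()]. The
#' `"fractional"` interpretation replaces the concentration change by the
#' fractional reduction `AQB * C_TOT`, omitting the PM2.5 level from the
#' first factor.
#'
#' @param aqb_pm25 AQB for PM2.5 (fraction).
#' @param c_tot Sum of sector contribution fractions for PM2.5.
#' @param pm25 City annual-mean PM2.5 (ug/m3).
#' @param death_rate All-cause death rate in the 30+ population (1/y).
#' @param frac_over_30 Fraction of population aged 30+.
#' @param rr_per_10 Relative risk per 10 ug/m3.
#' @param exposure_convention `"literal"` (default) or `"fractional"`.
#' @return Avoided premature deaths per inhabitant per year (vectorized).
#' @export
premature_deaths <- function(aqb_pm25, c_tot, pm25, death_rate, frac_over_30,
                             rr_per_10 = 1.062,
                             exposure_convention = c("literal", "fractional")) {
  exposure_convention <- match.arg(exposure_convention)
  af <- attributable_fraction(relative_risk(pm25, rr_per_10))
  exposure <- aqb_pm25 * c_tot
  if (exposure_convention == "literal") exposure <- exposure * pm25
  exposure * death_rate * frac_over_30 * af
}

#' Years of life saved from avoided premature deaths
#'
#' YLS = PD * YL: avoided deaths scaled by the country's mean years of
#' life lost per premature death.
#'
#' @param pd Avoided premature deaths (any bound, per capita or total).
#' @param yll_per_death Mean years of life lost per premature death (y).
#' @return Years of life saved per year (vectorized).
#' @export
years_of_life_saved <- function(pd, yll_per_death) {
  if (any(!is.na(yll_per_death) & yll_per_death <= 0)) {
    abort("yll_per_death must be > 0.")
  }
  pd * yll_per_death
}

#' Per-measure indicator table: CCB, AQB, premature deaths, years of life
#'
#' Computes the four indicators for every measure in the dataset (normally
#' the post-filter ES set): CCB, AQB for PM2.5 and NOx, the attributable
#' concentration change, and the health chain with (low, central, high)
#' bounds obtained by evaluating the relative risk at each element of
#' `rr`. City totals are the per-capita values multiplied by the city
#' population. Measures for which an indicator is undefined (zero sector
#' energy, empty SCE set, missing CO2 or non-positive city total CO2) are
#' skipped and logged in the `skipped` attribute.
#'
#' @param x A `cobenefit_data` object, normally after [filter_es()].
#' @param rr Named numeric vector `c(low, central, high)` of relative risks
#'   per 10 ug/m3; defaults to [rr_defaults()].
#' @param exposure_convention `"literal"` (default) or `"fractional"`; see
#'   [premature_deaths()].
#' @return A tibble with one row per measure: identifiers, `ccb`,
#'   `aqb_pm25`, `aqb_nox`, `c_tot_pm25`, `delta_pm25`, per-capita triples
#'   `pd_pc_*` and `yls_pc_*`, and city-total triples `pd_*` and `yls_*`
#'   (`* = low, central, high`). The skipped-measure log is in
#'   `attr(, "skipped")`.
#' @export
compute_indicators <- function(x, rr = rr_defaults(),
                               exposure_convention = c("literal", "fractional")) {
  stopifnot(inherits(x, "cobenefit_data"))
  exposure_convention <- match.arg(exposure_convention)
  stopifnot(all(c("low", "central", "high") %in% names(rr)))

  sce_tot <- x$sce |>
    dplyr::group_by(.data$city_id, .data$pollutant) |>
    dplyr::summarise(c_tot = sum(.data$fraction), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pollutant", values_from = "c_tot",
                       names_prefix = "c_tot_")
  sce_sec <- x$sce |>
    tidyr::pivot_wider(names_from = "pollutant", values_from = "fraction",
                       values_fill = 0, names_prefix = "c_sec_")
  for (col in c("c_tot_PM2.5", "c_tot_NOx")) {
    if (!col %in% names(sce_tot)) sce_tot[[col]] <- NA_real_
  }
  for (col in c("c_sec_PM2.5", "c_sec_NOx")) {
    if (!col %in% names(sce_sec)) sce_sec[[col]] <- 0
  }

  d <- x$measures |>
    dplyr::left_join(x$cities, by = "city_id") |>
    dplyr::left_join(x$sector_energy, by = c("city_id", "sector")) |>
    dplyr::left_join(sce_tot, by = "city_id") |>
    dplyr::left_join(sce_sec, by = c("city_id", "sector"))

  # a sector absent from a city's SCE table contributes nothing
  d$`c_sec_PM2.5` <- d$`c_sec_PM2.5` %na0% 0
  d$`c_sec_NOx` <- d$`c_sec_NOx` %na0% 0

  undefined <- dplyr::case_when(
    is.na(d$energy_mwh) | d$energy_mwh <= 0 ~ "sector energy zero or missing",
    is.na(d$`c_tot_PM2.5`) | d$`c_tot_PM2.5` <= 0 ~ "no PM2.5 source contributions",
    is.na(d$`c_tot_NOx`) | d$`c_tot_NOx` <= 0 ~ "no NOx source contributions",
    is.na(d$total_co2) | d$total_co2 <= 0 ~ "city total CO2 zero or missing",
    is.na(d$co2_reduction) ~ "missing CO2 reduction",
    is.na(d$energy_saved) ~ "missing energy saving",
    .default = NA_character_
  )
  skipped <- tibble::tibble(measure_id = d$measure_id[!is.na(undefined)],
                            reason = undefined[!is.na(undefined)])
  d <- d[is.na(undefined), ]

  out <- tibble::tibble(
    measure_id = d$measure_id,
    city_id = d$city_id,
    sector = d$sector,
    country = d$country,
    population = d$population,
    ccb = ccb(d$co2_reduction, d$total_co2),
    aqb_pm25 = aqb(d$energy_saved, d$energy_mwh,
                   d$`c_sec_PM2.5`, d$`c_tot_PM2.5`),
    aqb_nox = aqb(d$energy_saved, d$energy_mwh,
                  d$`c_sec_NOx`, d$`c_tot_NOx`),
    c_tot_pm25 = d$`c_tot_PM2.5`
  )
  out$delta_pm25 <- out$aqb_pm25 * out$c_tot_pm25 * d$pm25

  hp <- dplyr::left_join(
    tibble::tibble(country = d$country), x$health, by = "country")
  for (b in c("low", "central", "high")) {
    pd_pc <- premature_deaths(out$aqb_pm25, out$c_tot_pm25, d$pm25,
                              hp$death_rate, hp$frac_over_30,
                              rr_per_10 = rr[[b]],
                              exposure_convention = exposure_convention)
    out[[paste0("pd_pc_", b)]] <- pd_pc
    out[[paste0("yls_pc_", b)]] <- years_of_life_saved(pd_pc, hp$yll_per_death)
    out[[paste0("pd_", b)]] <- pd_pc * d$population
    out[[paste0("yls_", b)]] <- pd_pc * hp$yll_per_death * d$population
  }
  attr(out, "skipped") <- skipped
  attr(out, "rr") <- rr
  attr(out, "exposure_convention") <- exposure_convention
  out
}

#' Write an indicator table to CSV
#'
#' @param indicators Tibble from [compute_indicators()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(indicators, path) {
  readr::write_csv(indicators, path, na = "")
  invisible(path)
}
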