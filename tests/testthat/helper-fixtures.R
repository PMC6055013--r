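# Minimal well-formed raw tables (interchange schemas), built in code so
# tests can perturb individual cells.

one_city_tables <- function() {
  list(
    measures = tibble::tibble(
      measure_id = "M1", city_id = "A", sector = "Buildings",
      energy_saved_mwh = 100, renewable_mwh = NA_real_, co2_reduction_t = 27),
    bei = tibble::tibble(
      city_id = "A", country = "IT", population = 1e5,
      sector = c("Buildings", "Traffic", "Industry", "Other"),
      energy_mwh = c(1000, 800, 600, 100), total_co2_t = 250000),
    sce = tibble::tibble(
      city_id = "A", pollutant = rep(c("PM2.5", "NOx"), each = 4),
      sector = rep(c("Buildings", "Traffic", "Industry", "Other"), 2),
      fraction = c(0.30, 0.15, 0.10, 0.05, 0.25, 0.20, 0.10, 0.05)),
    aq = tibble::tibble(city_id = "A", pm25_ugm3 = 15, nox_ugm3 = 30),
    hi = tibble::tibble(country = "IT", death_rate = 0.01,
                        frac_over_30 = 0.6, yll_per_death = 10))
}

build_data <- function(tabs = one_city_tables(), ...) {
  mods <- list(...)
  for (nm in names(mods)) tabs[[nm]] <- mods[[nm]]
  cobenefit_data(tabs$measures, tabs$bei, tabs$sce, tabs$aq, tabs$hi)
}

write_tables_to <- function(tabs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(measures = "measures.csv", bei = "bei.csv", sce = "sce.csv",
                aq = "aq.csv", hi = "hi.csv")
  for (nm in names(paths)) {
    readr::write_csv(tabs[[nm]], file.path(dir, paths[[nm]]), na = "")
  }
  file.path(dir, unlist(paths, use.names = FALSE))
}

read_from_dir <- function(dir, ...) {
  read_cobenefit_tables(file.path(dir, "measures.csv"),
                        file.path(dir, "bei.csv"),
                        file.path(dir, "sce.csv"),
                        file.path(dir, "aq.csv"),
                        file.path(dir, "hi.csv"), ...)
}

# independent literal evaluation of the six-factor health chain
oracle_pd <- function(e_sav, e_sec, c_sec, c_tot, pm25, dr, p30, rr) {
  aqb_v <- (e_sav / e_sec) * (c_sec / c_tot)
  rf <- rr^(pm25 / 10)
  af <- (rf - 1) / rf
  aqb_v * c_tot * pm25 * dr * p30 * af
}
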