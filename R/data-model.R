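#' Assemble and validate a co-benefit analysis dataset
#'
#' Merges the five input tables of the analysis — mitigation measures,
#' baseline emission inventory (BEI), sector source-contribution estimates
#' (SCE), urban-background air quality, and country health parameters —
#' into one validated `cobenefit_data` object. Rows failing type or range
#' validation are dropped and logged; measures whose city lacks a BEI, air
#' quality or health record are dropped with a provenance entry, so the
#' returned object is referentially closed (every measure resolves to a
#' city, every city to health parameters).
#'
#' @param measures Data frame with columns `measure_id`, `city_id`,
#'   `sector`, `energy_saved_mwh`, `renewable_mwh`, `co2_reduction_t`.
#'   Energies are MWh/y, CO2 in tCO2-eq/y; empty cells mean "missing".
#' @param bei Data frame with columns `city_id`, `country`, `population`,
#'   `sector`, `energy_mwh`, `total_co2_t`: one row per city and sector,
#'   with the city-level population and total CO2 repeated on each row.
#' @param sce Data frame with columns `city_id`, `pollutant` (`"PM2.5"` or
#'   `"NOx"`), `sector`, `fraction`: the fraction of the city's
#'   urban-background concentration attributable to urban emissions of that
#'   sector. Fractions must lie in `[0, 1]` and sum to at most 1 over the
#'   four sectors (the remainder is non-urban background).
#' @param aq Data frame with columns `city_id`, `pm25_ugm3`, `nox_ugm3`:
#'   annual-mean urban-background concentrations.
#' @param hi Data frame with columns `country`, `death_rate` (all-cause
#'   deaths per person per year in the 30+ population), `frac_over_30`,
#'   `yll_per_death` (years of life lost per premature death).
#' @param sce_percent If `TRUE`, SCE fractions are given in percent and are
#'   divided by 100 on input.
#' @return A `cobenefit_data` object: a list of tibbles `measures`,
#'   `cities`, `sector_energy`, `sce`, `health`, plus a `provenance` log of
#'   merge and cleaning actions.
#' @seealso [read_cobenefit_tables()], [write_cobenefit_tables()],
#'   [classify_measures()]
#' @export
cobenefit_data <- function(measures, bei, sce, aq, hi, sce_percent = FALSE) {
  check_columns(measures, "measures", c("measure_id", "city_id", "sector",
                                        "energy_saved_mwh", "renewable_mwh",
                                        "co2_reduction_t"))
  check_columns(bei, "bei", c("city_id", "country", "population", "sector",
                              "energy_mwh", "total_co2_t"))
  check_columns(sce, "sce", c("city_id", "pollutant", "sector", "fraction"))
  check_columns(aq, "aq", c("city_id", "pm25_ugm3", "nox_ugm3"))
  check_columns(hi, "hi", c("country", "death_rate", "frac_over_30",
                            "yll_per_death"))
  prov <- new_provenance()

  ## country health parameters
  health <- tibble::as_tibble(hi) |>
    dplyr::transmute(country = as.character(.data$country),
                     death_rate = as.numeric(.data$death_rate),
                     frac_over_30 = as.numeric(.data$frac_over_30),
                     yll_per_death = as.numeric(.data$yll_per_death))
  ok <- !is.na(health$death_rate) & health$death_rate > 0 & health$death_rate < 1 &
    !is.na(health$frac_over_30) & health$frac_over_30 > 0 & health$frac_over_30 <= 1 &
    !is.na(health$yll_per_death) & health$yll_per_death > 0
  if (any(!ok)) {
    prov <- add_provenance(prov, "hi", "dropped invalid health rows", sum(!ok),
                           "death_rate/frac_over_30/yll_per_death out of range")
  }
  health <- health[ok, ]
  health <- dplyr::distinct(health, .data$country, .keep_all = TRUE)

  ## baseline emission inventory
  bei <- tibble::as_tibble(bei) |>
    dplyr::mutate(city_id = as.character(.data$city_id),
                  country = as.character(.data$country),
                  population = as.numeric(.data$population),
                  sector = normalize_sector(.data$sector),
                  energy_mwh = as.numeric(.data$energy_mwh),
                  total_co2_t = as.numeric(.data$total_co2_t))
  bad <- is.na(bei$population) | bei$population <= 0 |
    is.na(bei$energy_mwh) | bei$energy_mwh < 0
  if (any(bad)) {
    prov <- add_provenance(prov, "bei", "dropped invalid inventory rows",
                           sum(bad), "non-positive population or negative energy")
  }
  bei <- bei[!bad, ]
  cities <- bei |>
    dplyr::distinct(.data$city_id, .keep_all = TRUE) |>
    dplyr::select("city_id", "country", "population", total_co2 = "total_co2_t")
  sector_energy <- bei |>
    dplyr::group_by(.data$city_id, .data$sector) |>
    dplyr::summarise(energy_mwh = sum(.data$energy_mwh), .groups = "drop")

  ## air quality levels
  aq <- tibble::as_tibble(aq) |>
    dplyr::transmute(city_id = as.character(.data$city_id),
                     pm25 = as.numeric(.data$pm25_ugm3),
                     nox = as.numeric(.data$nox_ugm3))
  bad <- is.na(aq$pm25) | aq$pm25 <= 0 | is.na(aq$nox) | aq$nox <= 0
  if (any(bad)) {
    prov <- add_provenance(prov, "aq", "dropped invalid air-quality rows",
                           sum(bad), "non-positive concentration")
  }
  aq <- dplyr::distinct(aq[!bad, ], .data$city_id, .keep_all = TRUE)

  ## source contribution estimates
  sce <- tibble::as_tibble(sce) |>
    dplyr::transmute(city_id = as.character(.data$city_id),
                     pollutant = normalize_pollutant(.data$pollutant),
                     sector = normalize_sector(.data$sector),
                     fraction = as.numeric(.data$fraction))
  if (isTRUE(sce_percent)) sce$fraction <- sce$fraction / 100
  bad <- is.na(sce$pollutant) | is.na(sce$fraction) |
    sce$fraction < 0 | sce$fraction > 1
  if (any(bad)) {
    prov <- add_provenance(prov, "sce", "dropped invalid SCE rows", sum(bad),
                           "unknown pollutant or fraction outside [0,1]")
  }
  sce <- sce[!bad, ] |>
    dplyr::group_by(.data$city_id, .data$pollutant, .data$sector) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop")
  oversum <- sce |>
    dplyr::group_by(.data$city_id, .data$pollutant) |>
    dplyr::summarise(total = sum(.data$fraction), .groups = "drop") |>
    dplyr::filter(.data$total > 1 + 1e-12)
  if (nrow(oversum) > 0) {
    sce <- dplyr::anti_join(sce, oversum, by = c("city_id", "pollutant"))
    prov <- add_provenance(prov, "sce", "dropped SCE sets summing above 1",
                           nrow(oversum), "city/pollutant fraction sum > 1")
  }

  ## referential closure: cities need inventory + air quality + health
  n0 <- nrow(cities)
  cities <- dplyr::inner_join(cities, aq, by = "city_id")
  if (nrow(cities) < n0) {
    prov <- add_provenance(prov, "merge", "dropped cities without air-quality record",
                           n0 - nrow(cities), "no aq row")
  }
  n0 <- nrow(cities)
  cities <- dplyr::semi_join(cities, health, by = "country")
  if (nrow(cities) < n0) {
    prov <- add_provenance(prov, "merge", "dropped cities without health parameters",
                           n0 - nrow(cities), "country missing from hi table")
  }
  sector_energy <- dplyr::semi_join(sector_energy, cities, by = "city_id")
  sce <- dplyr::semi_join(sce, cities, by = "city_id")

  ## measures
  measures <- tibble::as_tibble(measures) |>
    dplyr::transmute(measure_id = as.character(.data$measure_id),
                     city_id = as.character(.data$city_id),
                     sector = normalize_sector(.data$sector),
                     energy_saved = as.numeric(.data$energy_saved_mwh),
                     renewable = as.numeric(.data$renewable_mwh),
                     co2_reduction = as.numeric(.data$co2_reduction_t))
  bad <- (!is.na(measures$energy_saved) & measures$energy_saved < 0) |
    (!is.na(measures$renewable) & measures$renewable < 0) |
    (!is.na(measures$co2_reduction) & measures$co2_reduction < 0)
  if (any(bad)) {
    prov <- add_provenance(prov, "measures", "dropped rows with negative values",
                           sum(bad), "negative energy or CO2 field")
  }
  measures <- measures[!bad, ]
  n0 <- nrow(measures)
  measures <- dplyr::semi_join(measures, cities, by = "city_id")
  if (nrow(measures) < n0) {
    prov <- add_provenance(prov, "merge", "dropped measures with unmatched city",
                           n0 - nrow(measures), "unmatched city")
  }
  measures$category <- NA_character_

  dup <- sum(duplicated(measures[c("city_id", "sector", "energy_saved",
                                   "renewable", "co2_reduction")]))
  if (dup > 0) {
    prov <- add_provenance(prov, "measures", "duplicate measures kept", dup,
                           "same city/sector/values")
  }

  out <- structure(list(measures = measures, cities = cities,
                        sector_energy = sector_energy, sce = sce,
                        health = health, provenance = prov),
                   class = "cobenefit_data")
  validate_cobenefit_data(out)
}

check_columns <- function(df, name, cols) {
  if (!is.data.frame(df)) stopf("`%s` must be a data frame.", name)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stopf("Table `%s` is missing required column(s): %s.",
          name, paste(missing, collapse = ", "))
  }
  invisible(df)
}

normalize_sector <- function(x) {
  x <- as.character(x)
  known <- match(tolower(x), tolower(SECTORS))
  out <- SECTORS[known]
  unknown <- is.na(known) & !is.na(x)
  if (any(unknown)) {
    warn(sprintf("%d unknown sector label(s) mapped to 'Other': %s",
                 sum(unknown),
                 paste(unique(x[unknown]), collapse = ", ")))
    out[unknown] <- "Other"
  }
  out
}

normalize_pollutant <- function(x) {
  x <- as.character(x)
  key <- tolower(gsub("[^a-z0-9]", "", tolower(x)))
  out <- rep(NA_character_, length(x))
  out[key %in% c("pm25", "pm2.5")] <- "PM2.5"
  out[key %in% c("nox", "no x")] <- "NOx"
  out
}

#' Check the internal invariants of a `cobenefit_data` object
#'
#' Verifies positivity and range invariants (populations, concentrations,
#' SCE fractions and their per-city sums) and referential closure (no
#' dangling `city_id` or `country`). Called by all constructors; exported
#' so that externally assembled or synthetic datasets can be checked too.
#'
#' @param x A `cobenefit_data` object.
#' @return `x`, invisibly; aborts with an informative message on violation.
#' @export
validate_cobenefit_data <- function(x) {
  stopifnot(inherits(x, "cobenefit_data"))
  m <- x$measures; ct <- x$cities
  if (any(ct$population <= 0, na.rm = TRUE)) abort("city population must be > 0")
  if (any(ct$pm25 <= 0 | ct$nox <= 0, na.rm = TRUE)) {
    abort("city concentrations must be > 0")
  }
  if (any(x$sector_energy$energy_mwh < 0, na.rm = TRUE)) {
    abort("sector energy must be >= 0")
  }
  if (any(x$sce$fraction < 0 | x$sce$fraction > 1)) {
    abort("SCE fractions must lie in [0, 1]")
  }
  sums <- x$sce |>
    dplyr::group_by(.data$city_id, .data$pollutant) |>
    dplyr::summarise(total = sum(.data$fraction), .groups = "drop")
  if (any(sums$total > 1 + 1e-9 | sums$total <= 0)) {
    abort("per-city SCE fraction sums must lie in (0, 1]")
  }
  if (any(m$energy_saved < 0 | m$renewable < 0 | m$co2_reduction < 0,
          na.rm = TRUE)) {
    abort("measure energy and CO2 fields must be >= 0 or missing")
  }
  if (!all(m$city_id %in% ct$city_id)) abort("dangling measure city_id")
  if (!all(ct$country %in% x$health$country)) abort("dangling city country code")
  if (!all(m$sector %in% SECTORS)) abort("unknown measure sector")
  invisible(x)
}

#' Read the five analysis tables from CSV files
#'
#' Reads and validates the measures, BEI, SCE, air-quality and health CSV
#' files (comma-separated, UTF-8, dot decimal, header row mandatory; empty
#' cells are missing values) and merges them with [cobenefit_data()].
#'
#' @param measures_path,bei_path,sce_path,aq_path,hi_path Paths to the five
#'   CSV files; see [cobenefit_data()] for the expected columns.
#' @inheritParams cobenefit_data
#' @return A validated `cobenefit_data` object.
#' @export
read_cobenefit_tables <- function(measures_path, bei_path, sce_path,
                                  aq_path, hi_path, sce_percent = FALSE) {
  paths <- c(measures = measures_path, bei = bei_path, sce = sce_path,
             aq = aq_path, hi = hi_path)
  for (i in seq_along(paths)) {
    if (!file.exists(paths[[i]])) {
      stopf("Input file for table `%s` not found: %s", names(paths)[i], paths[[i]])
    }
  }
  read1 <- function(p) readr::read_csv(p, col_types = readr::cols(),
                                       progress = FALSE,
                                       show_col_types = FALSE)
  cobenefit_data(measures = read1(measures_path), bei = read1(bei_path),
                 sce = read1(sce_path), aq = read1(aq_path),
                 hi = read1(hi_path), sce_percent = sce_percent)
}

#' Write a dataset back to the five-table CSV layout
#'
#' Inverse of [read_cobenefit_tables()] up to row order: the five files
#' written here re-read into a dataset with identical contents. Measure
#' categories are assigned by [classify_measures()], not stored in the
#' interchange format.
#'
#' @param x A `cobenefit_data` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_cobenefit_tables <- function(x, dir) {
  stopifnot(inherits(x, "cobenefit_data"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("Cannot create output directory: %s", dir)
  }
  if (file.access(dir, mode = 2) != 0) stopf("Output directory not writable: %s", dir)
  paths <- file.path(dir, c("measures.csv", "bei.csv", "sce.csv",
                            "aq.csv", "hi.csv"))
  names(paths) <- c("measures", "bei", "sce", "aq", "hi")

  measures <- x$measures |>
    dplyr::select("measure_id", "city_id", "sector",
                  energy_saved_mwh = "energy_saved",
                  renewable_mwh = "renewable",
                  co2_reduction_t = "co2_reduction")
  bei <- x$cities |>
    dplyr::inner_join(x$sector_energy, by = "city_id") |>
    dplyr::select("city_id", "country", "population", "sector",
                  "energy_mwh", total_co2_t = "total_co2")
  sce <- x$sce
  aq <- x$cities |>
    dplyr::select("city_id", pm25_ugm3 = "pm25", nox_ugm3 = "nox")
  hi <- x$health |>
    dplyr::select("country", "death_rate", "frac_over_30", "yll_per_death")

  readr::write_csv(measures, paths[["measures"]], na = "")
  readr::write_csv(bei, paths[["bei"]], na = "")
  readr::write_csv(sce, paths[["sce"]], na = "")
  readr::write_csv(aq, paths[["aq"]], na = "")
  readr::write_csv(hi, paths[["hi"]], na = "")
  invisible(paths)
}

#' @export
print.cobenefit_data <- function(x, ...) {
  cat("<cobenefit_data>\n")
  cat(sprintf("  measures: %d (%s)\n", nrow(x$measures),
              if (all(is.na(x$measures$category))) "unclassified"
              else paste(names(table(x$measures$category)),
                         table(x$measures$category),
                         sep = "=", collapse = ", ")))
  cat(sprintf("  cities:   %d in %d countries\n", nrow(x$cities),
              dplyr::n_distinct(x$cities$country)))
  cat(sprintf("  provenance entries: %d\n", nrow(x$provenance)))
  invisible(x)
}
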