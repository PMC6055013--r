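test_that("generation is deterministic under a fixed seed", {
  p <- generator_params(n_cities = 15, measures_per_city_mean = 10)
  g1 <- generate_cobenefit_data(p, seed = 99)
  g2 <- generate_cobenefit_data(p, seed = 99)
  expect_identical(g1$data$measures, g2$data$measures)
  expect_identical(g1$data$cities, g2$data$cities)
  expect_identical(g1$data$sce, g2$data$sce)
  expect_identical(g1$truth$emission_factors, g2$truth$emission_factors)
  g3 <- generate_cobenefit_data(p, seed = 100)
  expect_false(identical(g1$data$measures, g3$data$measures))
})

test_that("generated datasets satisfy all data-model invariants", {
  for (seed in c(1, 2)) {
    g <- generate_cobenefit_data(generator_params(n_cities = 30,
                                                  measures_per_city_mean = 12,
                                                  n_violators = 3),
                                 seed = seed)
    expect_no_error(validate_cobenefit_data(g$data))
    sums <- g$data$sce |>
      dplyr::group_by(city_id, pollutant) |>
      dplyr::summarise(total = sum(fraction), .groups = "drop")
    expect_true(all(sums$total > 0 & sums$total <= 1))
  }
})

test_that("sector shares of a large draw match the configured multinomial", {
  p <- generator_params(n_cities = 100, measures_per_city_mean = 20)
  g <- generate_cobenefit_data(p, seed = 12)
  m <- g$data$measures
  expect_gt(nrow(m), 1500)
  shares <- table(factor(m$sector, levels = c("Buildings", "Traffic",
                                              "Industry", "Other"))) / nrow(m)
  expect_equal(unname(as.numeric(shares)), c(0.54, 0.25, 0.19, 0.02),
               tolerance = 0.03 / 0.54) # absolute +-0.03 on the largest share
  expect_true(all(abs(as.numeric(shares) - c(0.54, 0.25, 0.19, 0.02)) < 0.03))
})

test_that("noiseless draws let the fit recover emission factors exactly", {
  p <- generator_params(n_cities = 20, measures_per_city_mean = 15,
                        co2_noise_log10_sd = 0,
                        category_fracs = c(ES = 1, REP = 0, MIX = 0,
                                           UNCLASSIFIED = 0))
  g <- generate_cobenefit_data(p, seed = 8)
  f <- filter_es(classify_measures(g$data))
  fits <- sectorwise_fits(f$measures, energy_saved, co2_reduction)
  for (s in c("Buildings", "Traffic", "Industry")) {
    row <- fits[fits$group == s, ]
    expect_equal(row$alpha, unname(g$truth$emission_factors[[s]]),
                 tolerance = 1e-12)
    expect_equal(row$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("energy savings span the configured decade range", {
  g <- generate_cobenefit_data(generator_params(n_cities = 80,
                                                measures_per_city_mean = 20),
                               seed = 21)
  e <- g$data$measures$energy_saved
  e <- e[!is.na(e) & e > 0]
  expect_gt(log10(max(e) / min(e)), 4) # wide dynamic range survives capping
})

test_that("slope-calibrated mode reproduces target slopes exactly without noise", {
  p <- recovery_validation_params()
  p$co2_noise_log10_sd <- 0
  g <- generate_cobenefit_data(p, seed = 3)
  ind <- compute_indicators(filter_es(classify_measures(g$data)))
  for (pol in c("pm25", "nox")) {
    targets <- p$slope_targets[[pol]]
    ff <- sectorwise_fits(ind, ccb, !!rlang::sym(paste0("aqb_", pol)))
    for (s in names(targets)) {
      row <- ff[ff$group == s, ]
      expect_equal(row$alpha, unname(targets[[s]]), tolerance = 1e-9)
      expect_equal(row$r_squared, 1, tolerance = 1e-9)
    }
  }
})

test_that("deliberate violators are injected and then caught by the filter", {
  p <- generator_params(n_cities = 20, measures_per_city_mean = 20,
                        n_violators = 8)
  g <- generate_cobenefit_data(p, seed = 17)
  f <- filter_es(classify_measures(g$data))
  expect_equal(classification_report(f)$excluded_exceedance, 8L)
})

test_that("infeasible slope targets are rejected", {
  # identical differences everywhere: no sector rescaling can reconcile them
  expect_error(
    generate_cobenefit_data(generator_params(
      n_cities = 2,
      slope_targets = list(
        pm25 = c(Buildings = 1, Traffic = 1, Industry = 1, Other = 1),
        nox = c(Buildings = 2, Traffic = 2, Industry = 2, Other = 2))),
      seed = 1),
    "Infeasible")
})

test_that("country fixture has 23 rows and known entries", {
  cs <- com_country_summary()
  expect_equal(nrow(cs), 23)
  it <- cs[cs$country == "IT", ]
  expect_equal(it$n_signatories, 34L)
  expect_equal(it$population, 11676675)
  expect_equal(it$n_es_measures, 597L)
  expect_equal(it$energy_saved_twh, 22.499)
  expect_equal(it$co2_reduction_mt, 5.689)
  se <- cs[cs$country == "SE", ]
  expect_equal(unlist(se[-1], use.names = FALSE),
               c(1, 112949, 3, 0.017, 0.008))
})

test_that("simulate_to_dir writes five tables plus a ground-truth record", {
  dir <- withr::local_tempdir()
  paths <- simulate_to_dir(dir, generator_params(n_cities = 8,
                                                 measures_per_city_mean = 5),
                           seed = 2)
  expect_true(all(file.exists(paths)))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$seed, 2)
  expect_equal(gt$emission_factors$Buildings, 0.269)
  d <- read_from_dir(dir)
  expect_gt(nrow(d$measures), 0)
})
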