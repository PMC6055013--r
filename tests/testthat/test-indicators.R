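test_that("CCB and AQB closed forms and error cases", {
  expect_equal(ccb(0, 250000), 0)
  expect_equal(ccb(250000, 250000), 1)
  expect_equal(ccb(5000, 250000), 0.02)
  expect_error(ccb(1, 0), "total CO2")

  expect_equal(aqb(0, 1000, 0.3, 0.5), 0)
  expect_equal(aqb(1000, 1000, 0.5, 0.5), 1) # ideal measure
  expect_equal(aqb(100, 1000, 0.3, 0.5), 0.06)
  expect_error(aqb(1, 0, 0.3, 0.5), "sector energy")
  expect_error(aqb(1, 10, 0.3, 0), "total urban contribution")
})

test_that("risk chain closed forms", {
  expect_equal(relative_risk(0, 1.062), 1)
  expect_equal(relative_risk(0, 1.5), 1)
  expect_equal(relative_risk(10, 1.062), 1.062)
  expect_equal(relative_risk(20, 1.062), 1.062^2)
  expect_error(relative_risk(-1), ">= 0")

  expect_equal(attributable_fraction(1), 0)
  expect_equal(attributable_fraction(2), 0.5)
  rf15 <- 1.062^1.5
  expect_equal(attributable_fraction(rf15), (rf15 - 1) / rf15)
  expect_error(attributable_fraction(0.9), ">= 1")

  # AF strictly increasing in PM2.5, tending to 0 at zero exposure
  pm <- seq(0, 60, by = 0.5)
  af <- attributable_fraction(relative_risk(pm, 1.062))
  expect_true(all(diff(af) > 0))
  expect_equal(af[1], 0)
})

test_that("premature deaths equal the literal six-factor product", {
  pd <- premature_deaths(aqb_pm25 = 0.06, c_tot = 0.5, pm25 = 15,
                         death_rate = 0.01, frac_over_30 = 0.6,
                         rr_per_10 = 1.062)
  af <- (1.062^1.5 - 1) / 1.062^1.5
  expect_equal(pd, 0.06 * 0.5 * 15 * 0.01 * 0.6 * af, tolerance = 1e-15)
  # fractional interpretation drops the concentration level from the product
  pdf_ <- premature_deaths(0.06, 0.5, 15, 0.01, 0.6, 1.062, "fractional")
  expect_equal(pdf_, pd / 15, tolerance = 1e-15)
  expect_equal(years_of_life_saved(2e-4, 10), 2e-3)
  expect_error(years_of_life_saved(1, 0), "yll_per_death")
})

test_that("pipeline indicators equal an independent evaluation on random measures", {
  set.seed(71)
  n <- 10000
  e_sec <- 10^runif(n, 3, 6)
  e_sav <- e_sec * runif(n)
  c_tot <- runif(n, 0.2, 0.9)
  c_sec <- c_tot * runif(n)
  pm25 <- runif(n, 5, 40)
  dr <- runif(n, 0.006, 0.015)
  p30 <- runif(n, 0.5, 0.7)
  yll <- runif(n, 8, 12)
  for (rr in c(1.04, 1.062, 1.083)) {
    got <- premature_deaths(aqb(e_sav, e_sec, c_sec, c_tot), c_tot, pm25,
                            dr, p30, rr)
    want <- oracle_pd(e_sav, e_sec, c_sec, c_tot, pm25, dr, p30, rr)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(years_of_life_saved(got, yll), got * yll)
  }
})

test_that("indicator table composes the individual operations and bounds are ordered", {
  d <- filter_es(classify_measures(toy_cobenefit_data()))
  ind <- compute_indicators(d)
  m1 <- ind[ind$measure_id == "M1", ]
  expect_equal(m1$ccb, 27 / 250000)
  expect_equal(m1$aqb_pm25, (100 / 1000) * (0.30 / 0.60))
  expect_equal(m1$aqb_nox, (100 / 1000) * (0.10 / 0.60))
  expect_equal(m1$delta_pm25, m1$aqb_pm25 * 0.60 * 15)
  expect_equal(m1$pd_pc_central,
               oracle_pd(100, 1000, 0.30, 0.60, 15, 0.01, 0.6, 1.062))
  expect_equal(m1$pd_central, m1$pd_pc_central * 1e5)
  expect_equal(m1$yls_central, m1$pd_central * 10)

  g <- generate_cobenefit_data(generator_params(n_cities = 25,
                                                measures_per_city_mean = 20),
                               seed = 4)
  ind <- compute_indicators(filter_es(classify_measures(g$data)))
  expect_true(all(ind$aqb_pm25 >= 0 & ind$aqb_pm25 <= 1))
  expect_true(all(ind$aqb_nox >= 0 & ind$aqb_nox <= 1))
  expect_true(all(ind$pd_low <= ind$pd_central & ind$pd_central <= ind$pd_high))
  expect_true(all(ind$yls_low <= ind$yls_central & ind$yls_central <= ind$yls_high))
  expect_true(all(ind$ccb >= 0))
})

test_that("indicators are homogeneous of degree one in the energy saved", {
  tabs <- one_city_tables()
  doubled <- tabs
  doubled$measures$energy_saved_mwh <- 200 # x2
  doubled$measures$co2_reduction_t <- 54   # CO2/energy ratio held fixed
  i1 <- compute_indicators(filter_es(classify_measures(build_data(tabs))))
  i2 <- compute_indicators(filter_es(classify_measures(build_data(doubled))))
  for (cc in c("ccb", "aqb_pm25", "aqb_nox", "delta_pm25",
               "pd_central", "pd_low", "pd_high", "yls_central")) {
    expect_equal(i2[[cc]], 2 * i1[[cc]], tolerance = 1e-12)
  }
})

test_that("measures with undefined indicators are skipped and logged", {
  tabs <- one_city_tables()
  tabs$bei$total_co2_t <- 0
  ind <- compute_indicators(filter_es(classify_measures(build_data(tabs))))
  expect_equal(nrow(ind), 0)
  skipped <- attr(ind, "skipped")
  expect_equal(skipped$measure_id, "M1")
  expect_match(skipped$reason, "total CO2")
})
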