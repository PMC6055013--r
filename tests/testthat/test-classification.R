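test_that("category assignment follows the zero-or-missing rule", {
  expect_equal(
    classify_category(c(500, 0, 0, 10, NA, 0), c(NA, 200, NA, 5, NA, 0)),
    c("ES", "REP", "UNCLASSIFIED", "MIX", "UNCLASSIFIED", "UNCLASSIFIED"))
  expect_error(classify_category(-1, 0), "non-negative")
})

test_that("every measure gets exactly one category and counts sum to the input", {
  g <- generate_cobenefit_data(generator_params(n_cities = 30,
                                                measures_per_city_mean = 20),
                               seed = 11)
  d <- classify_measures(g$data)
  expect_false(anyNA(d$measures$category))
  expect_true(all(d$measures$category %in% c("ES", "REP", "MIX", "UNCLASSIFIED")))
  f <- filter_es(d)
  rep <- classification_report(f)
  expect_equal(sum(rep$counts_by_category), nrow(d$measures))
  expect_equal(rep$final_es_count,
               rep$counts_by_category[["ES"]] - rep$excluded_count)
})

test_that("exceedance filter removes strictly-larger savings, keeps the boundary", {
  tabs <- one_city_tables()
  tabs$measures <- tibble::tibble(
    measure_id = c("M1", "M2", "M3"),
    city_id = "A", sector = "Buildings",
    energy_saved_mwh = c(1200, 1000, 999), # sector consumption is 1000
    renewable_mwh = NA_real_, co2_reduction_t = 1)
  f <- filter_es(build_data(tabs))
  rep <- classification_report(f)
  expect_equal(sort(f$measures$measure_id), c("M2", "M3"))
  expect_equal(rep$excluded_exceedance, 1L)
  expect_equal(rep$final_es_count, 2L)
})

test_that("an ES measure in a sector missing from the city's inventory is excluded separately", {
  tabs <- one_city_tables()
  tabs$bei <- tabs$bei[tabs$bei$sector != "Buildings", ]
  f <- filter_es(build_data(tabs))
  rep <- classification_report(f)
  expect_equal(rep$excluded_no_sector_energy, 1L)
  expect_equal(rep$excluded_exceedance, 0L)
  expect_equal(rep$final_es_count, 0L)
})

test_that("country summary rows are hand-countable and the total row equals column sums", {
  tabs <- one_city_tables()
  tabs$bei <- dplyr::bind_rows(
    tabs$bei, dplyr::mutate(tabs$bei, city_id = "B", population = 200))
  tabs$bei$population[tabs$bei$city_id == "A"] <- 100
  tabs$aq <- dplyr::bind_rows(tabs$aq,
                              tibble::tibble(city_id = "B", pm25_ugm3 = 12,
                                             nox_ugm3 = 20))
  tabs$measures <- tibble::tibble(
    measure_id = c("M1", "M2", "M3"),
    city_id = c("A", "A", "B"), sector = "Buildings",
    energy_saved_mwh = c(100, 50, 200), renewable_mwh = NA_real_,
    co2_reduction_t = c(30, 15, 60))
  cs <- summarize_by_country(filter_es(build_data(tabs)))
  it <- cs[cs$country == "IT", ]
  expect_equal(it$n_signatories, 2L)
  expect_equal(it$population, 300)
  expect_equal(it$n_es_measures, 3L)
  tot <- cs[cs$country == "Total", ]
  for (cc in c("n_signatories", "population", "n_es_measures",
               "energy_saved_twh", "co2_reduction_mt")) {
    expect_equal(tot[[cc]], sum(cs[[cc]][cs$country != "Total"]))
  }
})

test_that("sector shares sum to one, percents to 100, single sector renders 100%", {
  g <- generate_cobenefit_data(generator_params(n_cities = 20,
                                                measures_per_city_mean = 15),
                               seed = 2)
  ss <- summarize_by_sector(classify_measures(g$data))
  expect_equal(sum(ss$count_share), 1, tolerance = 1e-12)
  expect_equal(sum(ss$energy_share), 1, tolerance = 1e-12)
  expect_equal(sum(ss$count_pct), 100L)
  expect_equal(sum(ss$energy_pct), 100L)

  tabs <- one_city_tables()
  tabs$measures$sector <- "Traffic"
  ss1 <- summarize_by_sector(classify_measures(build_data(tabs)))
  expect_equal(ss1$count_pct[ss1$sector == "Traffic"], 100L)
})

test_that("largest-remainder percent rendering matches published share tables", {
  # 106/4220 = 2.51% would round to 3 independently; apportionment gives 2
  expect_equal(unname(integer_percent_shares(c(2275, 1054, 785, 106))),
               c(54L, 25L, 19L, 2L))
  expect_equal(unname(integer_percent_shares(c(1, 1, 1))), c(34L, 33L, 33L))
  expect_equal(sum(integer_percent_shares(runif(7))), 100L)
  expect_error(integer_percent_shares(c(-1, 2)), "non-negative")
})

test_that("filtering never increases per-sector totals", {
  g <- generate_cobenefit_data(generator_params(n_cities = 25,
                                                measures_per_city_mean = 15,
                                                n_violators = 5), seed = 3)
  d <- classify_measures(g$data)
  before <- summarize_by_sector(d)
  after <- summarize_by_sector(filter_es(d))
  expect_true(all(after$n_measures <= before$n_measures))
  expect_true(all(after$energy_saved_mwh <= before$energy_saved_mwh + 1e-9))
})
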