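test_that("through-origin fit matches its closed form and lm cross-check", {
  x <- c(1, 2, 3); y <- c(2, 4.1, 5.9)
  f <- fit_through_origin(x, y)
  expect_equal(f$alpha, 27.9 / 14)
  lmfit <- lm(y ~ 0 + x)
  expect_equal(f$alpha, unname(coef(lmfit)))
  expect_equal(f$se, unname(sqrt(diag(vcov(lmfit)))))
  expect_equal(unname(f$ci), unname(confint(lmfit)[1, ]))
  expect_equal(f$r_squared, summary(lmfit)$r.squared)
})

test_that("noiseless data are recovered exactly with a zero-width interval", {
  x <- 1:5
  f <- fit_through_origin(x, 2 * x)
  expect_equal(f$alpha, 2)
  expect_equal(f$r_squared, 1)
  expect_equal(f$ci, c(2, 2))
})

test_that("single points and degenerate designs are handled", {
  f <- fit_through_origin(1, 3)
  expect_equal(f$alpha, 3)
  expect_true(f$degenerate)
  expect_true(all(is.na(f$ci)))
  expect_error(fit_through_origin(c(0, 0), c(1, 2)), "all x are zero")
  expect_error(fit_through_origin(1:3, 1:2), "equal length")
})

test_that("t-interval coverage is nominal under homoscedastic Gaussian noise", {
  set.seed(20260922)
  n <- 40; alpha <- 2; reps <- 1000
  x <- runif(n, 1, 5)
  hits <- 0
  for (i in seq_len(reps)) {
    f <- fit_through_origin(x, alpha * x + rnorm(n, 0, 0.8))
    hits <- hits + (f$ci[1] <= alpha && alpha <= f$ci[2])
  }
  expect_gte(hits / reps, 0.93)
  expect_lte(hits / reps, 0.97)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # A = 1,2,3 and B = 2,3,4: SSB = 1.5, SSW = 4, df = 1 and 4, F = 1.5
  d <- data.frame(v = c(1, 2, 3, 2, 3, 4), g = rep(c("A", "B"), each = 3))
  a <- one_way_anova(d, v, g)
  expect_equal(a$f_stat, 1.5)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  expect_equal(a$p_value, pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(a$group_sizes, c(A = 3L, B = 3L))

  # identical distributions: F = 0, p = 1
  d2 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("A", "B"), each = 3))
  a2 <- one_way_anova(d2, v, g)
  expect_equal(a2$f_stat, 0)
  expect_equal(a2$p_value, 1)

  # location invariance
  a3 <- one_way_anova(dplyr::mutate(d, v = v + 100), v, g)
  expect_equal(a3$f_stat, a$f_stat)
})

test_that("undersized groups are dropped with a warning; <2 groups errors", {
  d <- data.frame(v = c(1, 2, 3, 2, 3, 4, 9),
                  g = c(rep(c("A", "B"), each = 3), "C"))
  expect_warning(a <- one_way_anova(d, v, g), "C")
  expect_equal(sort(names(a$group_sizes)), c("A", "B"))
  expect_error(
    suppressWarnings(one_way_anova(data.frame(v = c(1, 2, 3), g = c("A", "A", "B")),
                                   v, g)),
    "at least two groups")
})

test_that("ANOVA type-I error under the null is near the nominal 5%", {
  set.seed(777)
  reps <- 1000
  rej <- 0
  for (i in seq_len(reps)) {
    d <- data.frame(v = rnorm(60),
                    g = rep(c("A", "B", "C"), each = 20))
    rej <- rej + (one_way_anova(d, v, g)$p_value < 0.05)
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("sectorwise fits recover exact per-sector slopes and flag low R2", {
  d <- tibble::tibble(
    sector = rep(c("Buildings", "Traffic"), each = 20),
    x = rep(seq(0.1, 2, length.out = 20), 2))
  d$y <- ifelse(d$sector == "Buildings", 0.2 * d$x, 1.66 * d$x)
  ff <- sectorwise_fits(d, x, y)
  expect_equal(ff$alpha[ff$group == "Buildings"], 0.2)
  expect_equal(ff$alpha[ff$group == "Traffic"], 1.66)
  expect_equal(ff$r_squared[ff$group == "Traffic"], 1)
  expect_false(ff$low_r2[ff$group == "Traffic"])
  # pooled equals the per-sector fit when a single sector is present
  f1 <- sectorwise_fits(d[d$sector == "Traffic", ], x, y)
  expect_equal(f1$alpha[f1$group == "All"], f1$alpha[f1$group == "Traffic"])
  # one-observation group flagged degenerate
  d1 <- dplyr::bind_rows(d, tibble::tibble(sector = "Other", x = 1, y = 5))
  fd <- sectorwise_fits(d1, x, y)
  expect_true(fd$degenerate[fd$group == "Other"])
  expect_equal(fd$alpha[fd$group == "Other"], 5)
})

test_that("tidy and glance methods return one-row summaries", {
  f <- fit_through_origin(1:10, 2 * (1:10) + rnorm(10, 0, 0.1))
  expect_equal(tidy(f)$estimate, f$alpha)
  expect_equal(glance(f)$nobs, 10L)
  a <- one_way_anova(data.frame(v = c(1, 2, 3, 5, 6, 7),
                                g = rep(c("A", "B"), each = 3)), v, g)
  expect_equal(tidy(a)$statistic, a$f_stat)
  expect_equal(glance(a)$nobs, 6L)
})
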