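test_that("truth generation is reproducible and respects the scenario", {
  sc <- toy_scenario()
  t1 <- generate_truth(sc, seed = 5)
  t2 <- generate_truth(sc, seed = 5)
  expect_identical(t1$pi, t2$pi)
  expect_identical(t1$counts$y_true, t2$counts$y_true)
  t3 <- generate_truth(sc, seed = 6)
  expect_false(identical(t1$pi, t3$pi))
  expect_true(all(t1$pi > 0 & t1$pi < 1))
  expect_true(all(t1$counts$y_true <= t1$counts$n_true))
})

test_that("noise-free scenarios give deterministic prevalences", {
  sc <- toy_scenario()
  sc$sigma <- 1e-9
  sc$region_sd <- 0
  sc$time_hypers <- trend_hypers(0, 0, 0, 0.9)
  sc$age_time_hypers <- trend_hypers(0, 0, 0, 0.9)
  sc$sex_time_hypers <- trend_hypers(0, 0, 0, 0.9)
  p1 <- generate_truth(sc, seed = 1)$pi
  p2 <- generate_truth(sc, seed = 2)$pi
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("counts are binomial draws around the prevalences", {
  sc <- toy_scenario()
  tr <- generate_truth(sc, seed = 9)
  expect_equal(mean(tr$counts$y_true / tr$counts$n_true), mean(tr$pi),
               tolerance = 0.002)
})

test_that("survey sources concentrate on aggregated truth as noise vanishes", {
  sc <- toy_scenario()
  sc$survey_sample_size <- 1e9  # kappa -> 0
  tr <- generate_truth(sc, seed = 3)
  so <- generate_sources(tr, sc, seed = 4)
  agg <- dplyr::summarise(
    dplyr::group_by(tr$counts, .data$age, .data$sex, .data$year),
    y = sum(.data$y_true), .groups = "drop")
  j <- dplyr::inner_join(so$survey$data, agg,
                         by = c("age", "sex", "year"))
  expect_equal(j$value, j$y, tolerance = 1e-3)
})

test_that("the admin bias construction halves counts when gamma = log(1/2)", {
  sc <- toy_scenario()
  sc$gamma <- c(log(0.5), 0)
  sc$sigma_y <- 0.02
  tr <- generate_truth(sc, seed = 5)
  so <- generate_sources(tr, sc, seed = 6)
  j <- dplyr::inner_join(so$admin$data, tr$counts,
                         by = c("age", "sex", "region", "urban", "year"))
  r1 <- mean((j$value / j$y_true)[j$age == "a1"])
  r2 <- mean((j$value / j$y_true)[j$age == "a2"])
  expect_equal(r1, 0.5, tolerance = 0.02)
  expect_equal(r2, 1, tolerance = 0.02)
})

test_that("coverage gaps in the scenario are honoured", {
  sc <- prev_scenario()
  b <- simulate_bundle(sc, seed = 2)
  svy <- b$sources$survey$data
  expect_true(all(svy$year %in% sc$survey_years))
  expect_false(any(svy$year == 2004 & svy$age %in% c("2-4", "5-9")))
  expect_equal(sort(unique(b$sources$admin$data$year)), 2013:2019)
  ex <- b$sources$extra_survey$data
  expect_equal(unique(ex$year), 2001)
  expect_false("sex" %in% names(ex))
})

test_that("panel trends are straight lines when drift noise is off", {
  sc <- toy_scenario()
  sc$panel_time_hypers <- trend_hypers(0, 0, 0, 1)
  sc$panel_sigma <- 1e-6
  sc$panel_n_eff <- 5e6
  set.seed(8)
  panel <- prevfuse:::simulate_panel(sc)
  one <- dplyr::filter(panel, .data$country == "country_01",
                       .data$sex == "F")
  lo <- log(one$estimate / (1 - one$estimate))
  fitl <- lm(lo ~ one$year)
  expect_lt(summary(fitl)$sigma, 0.01)
})
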