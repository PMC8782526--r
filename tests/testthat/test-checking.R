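test_that("least-squares slopes match closed forms", {
  d <- tibble::tibble(g = "s1", year = 0:3, value = c(1, 2, 3, 4))
  expect_equal(slope_summaries(d)$slope, 1)
  dc <- tibble::tibble(g = "s1", year = 2000:2005, value = 7)
  expect_equal(slope_summaries(dc)$slope, 0)
  set.seed(12)
  dr <- tibble::tibble(g = rep(c("s1", "s2"), each = 6),
                       year = rep(2000:2005, 2), value = rnorm(12))
  got <- slope_summaries(dr)
  for (gg in c("s1", "s2")) {
    sub <- dr[dr$g == gg, ]
    expect_equal(got$slope[got$g == gg],
                 unname(coef(lm(value ~ year, sub))[2]))
  }
  single <- tibble::tibble(g = c("s1", "s2"), year = c(2000, 2000),
                           value = 1:2)
  expect_warning(out <- slope_summaries(
    dplyr::bind_rows(dr, tibble::tibble(g = "s3", year = 2000,
                                        value = 1))), "skipped")
  expect_false("s3" %in% out$g)
})

test_that("replicates are reproducible and preserve the observation mask", {
  fit <- toy_fit()
  r1 <- generate_replicate(fit, k = 5, seed = 9)
  r2 <- generate_replicate(fit, k = 5, seed = 9)
  expect_identical(r1$value, r2$value)
  r3 <- generate_replicate(fit, k = 5, seed = 10)
  expect_false(identical(r1$value, r3$value))
  adm <- purrr::keep(fit$datasets, ~ .x$kind == "admin")[[1]]$data
  expect_equal(nrow(r1), nrow(adm))
  expect_equal(r1[, c("age", "sex", "region", "urban", "year")],
               adm[, c("age", "sex", "region", "urban", "year")],
               ignore_attr = TRUE)
  expect_true(all(r1$value > 0))
})

test_that("replicate means reflect the drawn bias and noise", {
  fit <- toy_fit()
  # over many replicates, mean log replicate value tracks mean log true
  # count plus the age bias of the generating draw
  set.seed(2)
  ks <- sample(600, 30)
  ages <- fit$grid$dims$age
  diffs <- purrr::map_dfr(seq_along(ks), function(i) {
    dr <- prevfuse:::posterior_draw(fit, ks[i])
    rep <- generate_replicate(fit, ks[i], seed = 100 + i)
    mu <- linear_predictor(dr$effects, fit$design)
    cells <- grid_cells(fit$grid)
    j <- dplyr::left_join(rep, dplyr::mutate(cells, mu = mu),
                          by = c("age", "sex", "region", "urban",
                                 "year"))
    n <- fit$setup$n_true[j$cell]
    expected <- log(n * (1 / (1 + exp(-j$mu))))
    tibble::tibble(age = j$age,
                   gap = log(j$value) - expected -
                     dr$gamma[["admin"]][match(j$age, ages)])
  })
  gaps <- tapply(diffs$gap, diffs$age, mean)
  # fresh noise terms are mean zero; allow Monte Carlo slack
  expect_lt(max(abs(gaps)), 0.06)
})

test_that("replicate checks flag about the nominal rate for model data", {
  fit <- toy_fit()
  rc <- replicate_check(fit, K = 39, seed = 3)
  expect_equal(rc$expected_fraction, 0.05)
  expect_equal(rc$n_series, 8) # 2 ages x 2 sexes x 2 regions (1 urban)
  expect_true(rc$flagged_fraction >= 0 && rc$flagged_fraction <= 1)
  expect_true(all(rc$series$rank >= 1 & rc$series$rank <= 40))
  expect_warning(replicate_check(fit, K = 2, seed = 1), "coarse")
})

test_that("a sensitivity grid runs every combination and records failures", {
  sc <- toy_scenario()
  bundle <- simulate_bundle(sc, seed = 51)
  tr <- bundle$truth
  so <- bundle$sources
  weak <- prior_damped_trend()
  strong <- prior_damped_trend(
    tau_beta = prior_half_normal(0.006),
    tau_alpha = prior_half_normal(0.01),
    tau_delta = prior_half_normal(0.01))
  res <- sensitivity_grid(
    tr$grid,
    model_variants = list(survey_only = list(so$survey),
                          all_sources = list(so$survey, so$admin)),
    prior_variants = list(weak = weak, informative = strong),
    exposures = so$exposures,
    config = prev_config(chains = 1, warmup = 150, iter = 150, seed = 2))
  expect_equal(nrow(res), 4)
  expect_true(all(is.na(res$error)))
  expect_true(all(purrr::map_lgl(res$summaries,
                                 ~ is.data.frame(.x) && nrow(.x) > 0)))
  # a broken variant is recorded, not fatal
  res2 <- sensitivity_grid(
    tr$grid,
    model_variants = list(bad = list(so$survey)), # no exposures passed
    prior_variants = list(weak = weak),
    exposures = NULL,
    config = prev_config(chains = 1, warmup = 50, iter = 50, seed = 2))
  expect_false(is.na(res2$error[1]))
})
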