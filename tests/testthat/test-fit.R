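test_that("fits are reproducible given the seed", {
  g <- tiny_grid()
  cfg <- prev_config(chains = 1, warmup = 50, iter = 50, seed = 3)
  f1 <- suppressWarnings(prev_fit(g, config = cfg))
  f2 <- suppressWarnings(prev_fit(g, config = cfg))
  expect_identical(f1$chains[[1]]$hyper, f2$chains[[1]]$hyper)
  expect_identical(f1$chains[[1]]$theta, f2$chains[[1]]$theta)
})

test_that("a single-cell intercept model matches grid integration", {
  # one cell, one survey observation with small kappa: the posterior of
  # pi concentrates near y_est / n_true; oracle by 1-D quadrature over
  # logit prevalence with the latent count profiled at its mean
  g <- prev_grid("a", "s", years = 2000)
  terms <- term_structure(
    term_spec("(Intercept)", character(), prior_normal(0, 10)))
  n <- 1e5
  y_est <- 12000
  kappa <- 200
  ds <- survey_dataset(tibble::tibble(
    age = "a", sex = "s", region = "all", urban = "all", year = 2000,
    value = y_est, sd = kappa))
  expo <- tibble::tibble(age = "a", sex = "s", region = "all",
                         urban = "all", year = 2000, n_true = n)
  f <- suppressWarnings(prev_fit(
    g, terms, datasets = list(ds), exposures = expo,
    config = prev_config(chains = 2, warmup = 400, iter = 800,
                         seed = 11)))
  pd <- prevalence_draws(f)
  expect_equal(median(pd), y_est / n, tolerance = 0.02)
  # quadrature oracle: p(theta | data) with y integrated numerically
  th_g <- seq(-2.4, -1.9, length.out = 300)
  marg <- vapply(th_g, function(th) {
    p <- 1 / (1 + exp(-th))
    yg <- seq(n * p - 6000, n * p + 6000, length.out = 800)
    f_y <- exp(lgamma(n + 1) - lgamma(yg + 1) - lgamma(n - yg + 1) +
                 yg * log(p) + (n - yg) * log(1 - p))
    sum(f_y * dnorm(y_est, yg, kappa)) * (yg[2] - yg[1])
  }, 0)
  marg <- marg / sum(marg)
  m_oracle <- sum(th_g * marg)
  theta_draws <- log(pd / (1 - pd))
  expect_equal(mean(theta_draws), m_oracle, tolerance = 0.01)
  expect_equal(sd(theta_draws),
               sqrt(sum(th_g^2 * marg) - m_oracle^2), tolerance = 0.15)
})

test_that("with no data the fit reproduces the prior", {
  g <- tiny_grid(years = 2000:2007, data_until = 2005)
  f <- suppressWarnings(prev_fit(
    g, config = prev_config(chains = 2, warmup = 300, iter = 1200,
                            seed = 21)))
  hd <- hyper_draws(f)
  hn_mean <- sqrt(2 / pi)
  # half-normal(1) scale parameters
  expect_equal(mean(hd$sigma), hn_mean, tolerance = 0.08)
  expect_equal(mean(hd$year.tau_delta), hn_mean, tolerance = 0.15)
  # damping parameter: scaled Beta(2, 2) on [0.8, 1]
  expect_equal(mean(hd$year.phi), 0.9, tolerance = 0.01)
  expect_equal(sd(hd$year.phi), sqrt(0.04 / 20), tolerance = 0.1)
  ed <- effect_draws(f)
  expect_equal(sd(ed[["(Intercept)[(Intercept)]"]]), 10, tolerance = 1)
  # sum-to-zero age effect: marginal sd sqrt(1 - 1/2)
  expect_equal(sd(ed[["age[a1]"]]), sqrt(0.5), tolerance = 0.08)
  expect_equal(ed[["age[a1]"]], -ed[["age[a2]"]])
})

test_that("posterior aggregated counts track a survey source as kappa -> 0", {
  sc <- toy_scenario()
  sc$survey_sample_size <- 4e8 # relative kappa ~ 1e-3 of the estimate
  bundle <- simulate_bundle(sc, seed = 41)
  tr <- bundle$truth
  so <- bundle$sources
  f <- suppressWarnings(prev_fit(
    tr$grid, default_terms(tr$grid), datasets = list(so$survey),
    exposures = so$exposures,
    config = prev_config(chains = 1, warmup = 250, iter = 250,
                         seed = 13)))
  pd <- prevalence_draws(f)
  cells <- grid_cells(tr$grid)
  svy <- so$survey$data
  n_cell <- sc$n_true_per_cell
  for (r in sample(nrow(svy), 4)) {
    j <- which(cells$age == svy$age[r] & cells$sex == svy$sex[r] &
                 cells$year == svy$year[r])
    post_agg <- median(pd[, j, drop = FALSE] %*% rep(n_cell, length(j)))
    expect_equal(post_agg, svy$value[r], tolerance = 0.01 * svy$value[r])
  }
})

test_that("impossible inputs are rejected", {
  g <- tiny_grid()
  ds <- survey_dataset(tibble::tibble(
    age = "a1", sex = "F", year = 2000, value = 10, sd = 1))
  expect_error(prev_fit(g, datasets = list(ds)), "exposures")
  expo <- dplyr::mutate(grid_cells(g)[, c("age", "sex", "region",
                                          "urban", "year")],
                        n_true = 100)
  adm_big <- admin_dataset(tibble::tibble(
    age = "a1", sex = "F", region = "all", urban = "all", year = 2000,
    value = 150))
  expect_error(prev_fit(g, datasets = list(adm_big), exposures = expo),
               "exposure")
})
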