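test_that("interval inversion yields the stated effective counts", {
  ec <- panel_counts_from_interval(0.2, 0.2 - 1.96 * 0.04,
                                   0.2 + 1.96 * 0.04)
  expect_equal(ec$n_eff, 0.16 / 0.04^2, tolerance = 1e-4)
  expect_equal(ec$y_eff, 0.2 * ec$n_eff)
  # halving the width quadruples the effective size
  ec2 <- panel_counts_from_interval(0.2, 0.2 - 1.96 * 0.02,
                                    0.2 + 1.96 * 0.02)
  expect_equal(ec2$n_eff / ec$n_eff, 4, tolerance = 1e-6)
  # asymmetric intervals are accepted with a message, same width rule
  expect_message(
    ec3 <- panel_counts_from_interval(0.2, 0.2 - 0.06, 0.2 + 0.1),
    "asymmetric")
  se <- 0.16 / (2 * qnorm(0.975))
  expect_equal(ec3$n_eff, 0.2 * 0.8 / se^2)
  expect_error(panel_counts_from_interval(0.2, 0.3, 0.25), "degenerate")
})

test_that("half-normal moment matching is exact and self-consistent", {
  expect_equal(approximate_half_normal(rep(1, 100))$sd, 1)
  set.seed(21)
  draws <- abs(rnorm(1e6, 0, 0.0054))
  expect_equal(approximate_half_normal(draws)$sd, 0.0054,
               tolerance = 0.01)
  expect_error(approximate_half_normal(c(-0.1, 0.2, 0.3)), "nonnegative")
  expect_warning(out <- approximate_half_normal(rep(0, 100)),
                 "degenerate")
  expect_equal(out$sd, 0)
})

test_that("phi moment matching recovers Beta parameters", {
  set.seed(22)
  u <- runif(2e5)
  pr <- approximate_phi_prior(0.8 + 0.2 * u)
  expect_equal(pr$a, 1, tolerance = 0.02)
  expect_equal(pr$b, 1, tolerance = 0.02)
  u2 <- rbeta(2e5, 2, 2)
  pr2 <- approximate_phi_prior(0.8 + 0.2 * u2)
  expect_equal(pr2$a, 2, tolerance = 0.05)
  expect_equal(pr2$b, 2, tolerance = 0.05)
  expect_error(approximate_phi_prior(c(0.7, 0.9)), "outside")
  expect_error(approximate_phi_prior(rep(0.9, 50)), "zero-variance")
})

test_that("variance inflation scales correctly and composes", {
  h <- trend_hyperpriors(
    tau_beta = prior_half_normal(0.0054),
    tau_alpha = prior_half_normal(0.01),
    tau_delta = prior_half_normal(0.02),
    phi = prior_scaled_beta(2, 2, 0.8, 1)
  )
  h2 <- inflate_prior(h, 2)
  expect_equal(h2$tau_beta$sd, 0.0054 * sqrt(2))
  expect_identical(inflate_prior(h, 1), h)
  # Beta inflation preserves the mean and doubles the variance
  bmean <- function(p) p$a / (p$a + p$b)
  bvar <- function(p) bmean(p) * (1 - bmean(p)) / (p$a + p$b + 1)
  expect_equal(bmean(h2$phi), bmean(h$phi))
  expect_equal(bvar(h2$phi), 2 * bvar(h$phi))
  # factor 2 twice equals factor 4
  h22 <- inflate_prior(inflate_prior(h, 2), 2)
  h4 <- inflate_prior(h, 4)
  expect_equal(h22$tau_delta$sd, h4$tau_delta$sd)
  expect_equal(h22$phi$a, h4$phi$a, tolerance = 1e-10)
  expect_equal(h22$inflation, h4$inflation)
  # requesting more variance than the mean allows clamps with a warning
  skew <- trend_hyperpriors(prior_half_normal(1), prior_half_normal(1),
                            prior_half_normal(1),
                            prior_scaled_beta(0.2, 0.2, 0.8, 1))
  expect_warning(inflate_prior(skew, 4), "clamp")
})

test_that("panel preconditions are enforced", {
  one_country <- tibble::tibble(country = "c1", sex = "F",
                                year = 2000:2010,
                                estimate = 0.1, lower = 0.08,
                                upper = 0.12)
  expect_error(fit_panel_model(one_country), "two countries")
  short <- tibble::tibble(country = c("c1", "c2"), sex = "F",
                          year = 2000, estimate = 0.1, lower = 0.08,
                          upper = 0.12)
  expect_error(fit_panel_model(short), "three years")
})

test_that("panel fitting recovers trend hyperparameters", {
  # panel generated with known hypers; the extracted posteriors should
  # track the truth (checked loosely on the best-identified parameters)
  sc <- prev_scenario(panel_countries = 20, panel_years = 2000:2019,
                      panel_n_eff = 5000,
                      panel_time_hypers = trend_hypers(0.005, 0.01,
                                                       0.02, 0.9))
  set.seed(14)
  panel <- prevfuse:::simulate_panel(sc)
  out <- suppressWarnings(extract_panel_hyperpriors(
    panel, config = prev_config(chains = 2, warmup = 300, iter = 300,
                                seed = 2), inflate = 1))
  s <- out$samples
  expect_true(all(c("tau_beta", "tau_alpha", "tau_delta", "phi") %in%
                    names(s)))
  expect_true(all(s$phi >= 0.8 & s$phi <= 1))
  # the extracted half-normal sds are positive and of sane magnitude
  expect_gt(out$hyperpriors$tau_delta$sd, 0)
  expect_lt(out$hyperpriors$tau_delta$sd, 0.3)
  # posterior intervals for the drift-noise sd should cover the truth
  expect_true(quantile(s$tau_delta, 0.025) < 0.02)
  expect_true(quantile(s$tau_delta, 0.995) > 0.005)
})
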