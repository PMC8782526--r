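test_that("scaled inverse-chi-squared quantiles match the chi-squared oracle", {
  spec <- prior_scaled_inv_chisq(df = 30, scale2 = 0.015)
  # central 95% interval reproduces the documented calibration endpoints
  ci <- central_interval(spec, 0.95)
  expect_equal(round(unname(ci), 3), c(0.010, 0.027))
  # oracle: nu * s^2 / chi-squared quantile
  for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(scaled_inv_chisq_quantile(spec, q),
                 30 * 0.015 / qchisq(1 - q, 30))
  }
  expect_error(scaled_inv_chisq_quantile(spec, 1.2), "0, 1")
})

test_that("scaled inverse-chi-squared quantiles invert the CDF", {
  # numeric-integration oracle over a grid of (nu, s2, q)
  for (nu in c(5, 30)) {
    for (s2 in c(0.015, 0.4)) {
      spec <- prior_scaled_inv_chisq(nu, s2)
      for (q in c(0.05, 0.5, 0.95)) {
        x <- scaled_inv_chisq_quantile(spec, q)
        cdf <- integrate(function(v)
          exp(prevfuse:::ldens_scaled_inv_chisq(v, nu, s2)),
          lower = 0, upper = x, rel.tol = 1e-10)$value
        expect_equal(cdf, q, tolerance = 1e-6)
      }
    }
  }
})

test_that("scaled inverse-chi-squared mean matches Monte Carlo", {
  spec <- prior_scaled_inv_chisq(df = 10, scale2 = 0.2)
  set.seed(1)
  draws <- prevfuse:::draw_prior(spec, 2e5)
  expect_equal(mean(draws), 10 * 0.2 / (10 - 2), tolerance = 0.02)
})

test_that("central intervals are nested and collapse to the median", {
  spec <- prior_scaled_inv_chisq(30, 0.015)
  i50 <- central_interval(spec, 0.5)
  i95 <- central_interval(spec, 0.95)
  expect_lt(i95[["lo"]], i50[["lo"]])
  expect_gt(i95[["hi"]], i50[["hi"]])
  i_tiny <- central_interval(spec, 1e-6)
  med <- scaled_inv_chisq_quantile(spec, 0.5)
  expect_equal(unname(i_tiny[["lo"]]), med, tolerance = 1e-4)
  expect_equal(unname(i_tiny[["hi"]]), med, tolerance = 1e-4)
})

test_that("prior densities match closed forms", {
  expect_equal(prevfuse:::ldens_half_normal(0.3, 1),
               log(2) + dnorm(0.3, 0, 1, log = TRUE))
  expect_equal(prevfuse:::ldens_half_normal(-0.1, 1), -Inf)
  p <- prior_scaled_beta(2, 2, 0.8, 1)
  u <- (0.9 - 0.8) / 0.2
  expect_equal(prevfuse:::ldens_scaled_beta(0.9, p),
               dbeta(u, 2, 2, log = TRUE) - log(0.2))
  expect_equal(prevfuse:::ldens_scaled_beta(0.8, p), -Inf)
  expect_error(prior_normal(0, -1))
  expect_error(prior_scaled_beta(0, 2))
})

test_that("log_prior sums term densities and hits boundaries correctly", {
  g <- tiny_grid()
  terms <- default_terms(g)
  d <- build_design(terms, g)
  set.seed(2)
  effects <- lapply(d, function(tm) rnorm(tm$n_levels, 0, 0.1))
  nT <- length(g$dims$year)
  mk_trend <- function(nc) list(
    alpha = matrix(rnorm(nc * (nT + 1), 0, 0.1), nc),
    delta = matrix(rnorm(nc * (nT + 1), 0, 0.05), nc),
    hypers = trend_hypers(0.1, 0.1, 0.05, 0.9)
  )
  st <- system_state(
    effects = effects, sigma = 0.2,
    theta = rnorm(g$n_cells, -2, 0.3),
    trend = list(year = mk_trend(1), `age:year` = mk_trend(2),
                 `sex:year` = mk_trend(2)),
    hier_tau = list(region = 0.3, urban = 0.2)
  )
  lp <- log_prior(st, d)
  expect_true(is.finite(lp))
  # independent per-density oracle
  oracle <- 0
  oracle <- oracle + dnorm(effects[["(Intercept)"]], 0, 10, log = TRUE)
  for (nm in c("age", "sex", "age:sex")) {
    oracle <- oracle + sum(dnorm(effects[[nm]], 0, 1, log = TRUE))
  }
  for (nm in c("region", "urban")) {
    tau <- st$hier_tau[[nm]]
    oracle <- oracle + sum(dnorm(effects[[nm]], 0, tau, log = TRUE)) +
      log(2) + dnorm(tau, 0, 1, log = TRUE)
  }
  for (nm in c("year", "age:year", "sex:year")) {
    tr <- st$trend[[nm]]
    h <- tr$hypers
    nc <- nrow(tr$alpha)
    bmat <- matrix(effects[[nm]], nc, nT)
    al <- tr$alpha
    de <- tr$delta
    for (cc in seq_len(nc)) {
      oracle <- oracle +
        sum(dnorm(bmat[cc, ], al[cc, -1], h$tau_beta, log = TRUE)) +
        sum(dnorm(al[cc, -1], al[cc, -(nT + 1)] + de[cc, -(nT + 1)],
                  h$tau_alpha, log = TRUE)) +
        sum(dnorm(de[cc, -1], h$phi * de[cc, -(nT + 1)], h$tau_delta,
                  log = TRUE)) +
        dnorm(al[cc, 1], 0, 1, log = TRUE) +
        dnorm(de[cc, 1], 0, 1, log = TRUE)
    }
    oracle <- oracle +
      log(2) + dnorm(h$tau_beta, 0, 1, log = TRUE) +
      log(2) + dnorm(h$tau_alpha, 0, 1, log = TRUE) +
      log(2) + dnorm(h$tau_delta, 0, 1, log = TRUE) +
      dbeta((h$phi - 0.8) / 0.2, 2, 2, log = TRUE) - log(0.2)
  }
  mu <- linear_predictor(effects, d)
  oracle <- oracle + sum(dnorm(st$theta, mu, st$sigma, log = TRUE)) +
    log(2) + dnorm(st$sigma, 0, 1, log = TRUE)
  expect_equal(lp, oracle, tolerance = 1e-10)

  # phi exactly at the range boundary has zero prior density
  st2 <- st
  st2$trend$year$hypers <- trend_hypers(0.1, 0.1, 0.05, 0.8)
  expect_equal(log_prior(st2, d), -Inf)
})
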