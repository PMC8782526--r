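test_that("interval summaries follow the linear-interpolation quantile rule", {
  s <- summary_intervals(1:100, levels = c(0.5, 0.95))
  expect_equal(unname(s["median"]), 50.5)
  expect_equal(unname(s["lower_50"]), quantile(1:100, 0.25, names = FALSE))
  expect_equal(unname(s["lower_50"]), 25.75)
  expect_equal(unname(s["upper_50"]), 75.25)
  # constant draws give zero-width intervals at the constant
  s0 <- summary_intervals(rep(3.2, 50))
  expect_true(all(s0 == 3.2))
  # nesting: 50% inside 95%
  set.seed(5)
  x <- rnorm(1000)
  s1 <- summary_intervals(x)
  expect_lt(s1["lower_95"], s1["lower_50"])
  expect_gt(s1["upper_95"], s1["upper_50"])
})

test_that("prevalence summaries cover the full grid with nested intervals", {
  fit <- toy_fit()
  sm <- summarise_prevalence(fit)
  expect_equal(nrow(sm), fit$grid$n_cells)
  expect_true(all(sm$lower_95 <= sm$lower_50))
  expect_true(all(sm$lower_50 <= sm$median))
  expect_true(all(sm$median <= sm$upper_50))
  expect_true(all(sm$upper_50 <= sm$upper_95))
  expect_true(all(sm$lower_95 >= 0 & sm$upper_95 <= 1))
  fc <- forecast_summaries(fit)
  expect_true(all(fc$forecast))
  expect_equal(nrow(fc),
               sum(grid_cells(fit$grid)$forecast))
})

test_that("split-chain diagnostics match the textbook formulas", {
  set.seed(6)
  n <- 400
  # identical-distribution white-noise chains: statistic near 1
  x_good <- cbind(rnorm(n), rnorm(n))
  expect_lt(prevfuse:::split_rhat(x_good), 1.02)
  # chains with different fixed means diverge
  x_bad <- cbind(rnorm(n, 0), rnorm(n, 5))
  expect_gt(prevfuse:::split_rhat(x_bad), 2)
  # mixed case against the formula computed independently
  x <- cbind(rnorm(n, 0, 1), rnorm(n, 0.3, 1.2))
  h <- n %/% 2
  sp <- cbind(x[1:h, ], x[(n - h + 1):n, ])
  W <- mean(apply(sp, 2, var))
  B <- h * var(colMeans(sp))
  oracle <- sqrt(((h - 1) / h * W + B / h) / W)
  expect_equal(prevfuse:::split_rhat(x), oracle, tolerance = 1e-12)
  # white noise has effective size close to the number of draws
  expect_gt(prevfuse:::split_ess(x_good), 0.5 * 2 * n)
})

test_that("the convergence report flags by configured thresholds", {
  fit <- toy_fit()
  rep <- convergence_report(fit)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(rep)))
  expect_gt(nrow(rep), 10)
  expect_type(attr(rep, "pass"), "logical")
  one_chain <- fit
  one_chain$chains <- one_chain$chains[1]
  one_chain$config$chains <- 1L
  expect_error(convergence_report(one_chain), "2 chains")
})

test_that("tidy and glance expose parameter and fit-level summaries", {
  fit <- toy_fit()
  td <- tidy(fit)
  expect_true(all(c("parameter", "median", "lower_95", "upper_95",
                    "rhat", "ess") %in% names(td)))
  expect_true("sigma" %in% td$parameter)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$chains, 2L)
  expect_equal(gl$n_draws, 600L)
  expect_true(is.finite(gl$max_rhat))
})

test_that("aggregate prevalence produces one nested-interval row per year", {
  fit <- toy_fit()
  agg <- aggregate_prevalence(fit)
  expect_equal(nrow(agg), length(fit$grid$dims$year))
  expect_true(all(agg$lower_95 <= agg$median & agg$median <= agg$upper_95))
})

test_that("plot builders return ggplot objects", {
  fit <- toy_fit()
  p1 <- plot_prevalence(aggregate_prevalence(fit))
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(fit)
  expect_s3_class(p2, "ggplot")
})
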