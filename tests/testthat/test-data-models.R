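test_that("effective counts reproduce design-based mean and variance", {
  # design effect 1: raw counts come back unchanged
  ec <- effective_counts(0.3, 0.3 * 0.7 / 200)
  expect_equal(ec$n_eff, 200)
  expect_equal(ec$y_eff, 60)
  # doubling the variance halves the effective sample size
  ec2 <- effective_counts(0.3, 2 * 0.3 * 0.7 / 200)
  expect_equal(ec2$n_eff, 100)
  ec3 <- effective_counts(0.5, 0.00125)
  expect_equal(ec3$n_eff, 200)
  expect_equal(ec3$y_eff, 100)
  # invariance to the scale of the weights: only (p_hat, var) matter
  expect_identical(effective_counts(0.3, 0.001),
                   effective_counts(0.3, 0.001))
  expect_error(effective_counts(0, 0.1), "clamp")
  expect_error(effective_counts(0.5, 0), "positive")
  expect_equal(clamp_proportion(0, 100), 1 / 200)
  expect_equal(clamp_proportion(1, 100), 1 - 1 / 200)
})

test_that("continuous binomial log-density extends dbinom", {
  expect_equal(lbinom_cont(3, 10, 0.4), dbinom(3, 10, 0.4, log = TRUE))
  expect_equal(lbinom_cont(0, 1, 0.5), log(0.5))
  expect_equal(lbinom_cont(5, 5, 1), 0) # y = n with pi -> 1
  expect_error(lbinom_cont(11, 10, 0.4), "0, n")
  expect_equal(system_loglik(c(0, 3), c(1, 10), c(0.5, 0.4)),
               log(0.5) + dbinom(3, 10, 0.4, log = TRUE))
})

test_that("aggregation conserves totals", {
  counts <- tidyr::expand_grid(age = c("a1", "a2"), sex = c("F", "M"),
                               region = c("r1", "r2"))
  counts$y_true <- c(3, 4, 1, 2, 5, 6, 7, 8)
  agg <- aggregate_true_counts(counts, "sex")
  expect_equal(sum(agg$y_true), sum(counts$y_true))
  expect_equal(agg$y_true[agg$age == "a1" & agg$region == "r1"],
               3 + 1)
  expect_identical(aggregate_true_counts(counts, character()), counts)
  all_summed <- aggregate_true_counts(counts, c("age", "sex", "region"))
  expect_equal(all_summed$y_true, 36)
  expect_error(aggregate_true_counts(counts, "province"), "province")
})

test_that("survey log-likelihood matches the normal oracle", {
  ds <- survey_dataset(
    tibble::tibble(age = c("a1", "a2"), year = 2000,
                   value = c(10, 20), sd = c(2, 3)),
    aggregate = "sex")
  y_true <- tibble::tibble(age = c("a1", "a2"), year = 2000,
                           y_true = c(10, 18))
  # at the mode each cell contributes -log(kappa * sqrt(2 pi))
  y_mode <- tibble::tibble(age = c("a1", "a2"), year = 2000,
                           y_true = c(10, 20))
  expect_equal(survey_loglik(y_mode, ds),
               sum(-log(c(2, 3) * sqrt(2 * pi))))
  expect_equal(survey_loglik(y_true, ds),
               dnorm(10, 10, 2, log = TRUE) + dnorm(20, 18, 3, log = TRUE))
  empty <- survey_dataset(tibble::tibble(age = character(),
                                         year = integer(),
                                         value = numeric(),
                                         sd = numeric()))
  expect_equal(survey_loglik(y_true, empty), 0)
})

test_that("admin log-likelihood matches the log-normal oracle", {
  y_true <- tibble::tibble(age = c("a1", "a1", "a2"), year = 2000:2002,
                           y_true = c(100, 120, 80))
  gam <- c(a1 = -0.2, a2 = 0.1)
  ds <- admin_dataset(tibble::tibble(
    age = c("a1", "a1", "a2"), year = 2000:2002,
    value = y_true$y_true * exp(gam[c("a1", "a1", "a2")])))
  # bias exactly absorbed: per-cell contribution is the normal mode
  expect_equal(
    admin_loglik(y_true, ds, gamma = gam, sigma_y = 0.2,
                 sigma_gamma = 1),
    3 * (-log(0.2 * sqrt(2 * pi))) + sum(dnorm(gam, 0, 1, log = TRUE)))
  # gamma = 0 and value = y_true is also the mode
  ds0 <- admin_dataset(tibble::tibble(age = "a1", year = 2000, value = 100))
  expect_equal(
    admin_loglik(y_true[1, ], ds0, gamma = c(a1 = 0), sigma_y = 0.3,
                 sigma_gamma = 1),
    -log(0.3 * sqrt(2 * pi)) + dnorm(0, 0, 1, log = TRUE))
  # random case against an explicit log-normal oracle
  set.seed(8)
  vals <- exp(log(y_true$y_true) + rnorm(3, 0, 0.4))
  dsr <- admin_dataset(tibble::tibble(age = y_true$age,
                                      year = y_true$year, value = vals))
  got <- admin_loglik(y_true, dsr, gamma = gam, sigma_y = 0.4,
                      sigma_gamma = 0.7)
  oracle <- sum(dnorm(log(vals),
                      log(y_true$y_true) + gam[y_true$age], 0.4,
                      log = TRUE)) +
    sum(dnorm(gam, 0, 0.7, log = TRUE))
  expect_equal(got, oracle)
  # zero latent count on an observed admin cell is a hard error
  y_bad <- y_true
  y_bad$y_true[1] <- 0
  expect_error(admin_loglik(y_bad, dsr, gam, 0.4, 0.7), "positive")
})

test_that("combined likelihood is a sum over sources, order-invariant", {
  counts <- tidyr::expand_grid(age = c("a1", "a2"), sex = c("F", "M"),
                               year = 2000:2001)
  set.seed(3)
  counts$y_true <- rpois(nrow(counts), 100)
  svy <- survey_dataset(tibble::tibble(
    age = "a1", sex = "F", year = 2000, value = 105, sd = 4))
  svy2 <- survey_dataset(tibble::tibble(age = "a2", year = 2001,
                                        value = 190, sd = 9),
                         aggregate = "sex", name = "pooled")
  adm <- admin_dataset(tibble::tibble(
    age = c("a1", "a2"), sex = "M", year = 2001,
    value = c(80, 95)))
  params <- list(gamma = c(a1 = -0.1, a2 = -0.2), sigma_y = 0.3,
                 sigma_gamma = 1)
  parts <- c(
    survey_loglik(counts, svy),
    survey_loglik(aggregate_true_counts(counts, "sex"), svy2),
    admin_loglik(counts, adm, params$gamma, params$sigma_y,
                 params$sigma_gamma)
  )
  tot <- combined_loglik(counts, list(svy, svy2, adm), params)
  expect_equal(tot, sum(parts))
  expect_equal(combined_loglik(counts, list(adm, svy2, svy), params), tot)
  expect_equal(combined_loglik(counts, list()), 0)
  expect_equal(combined_loglik(counts, list(svy)),
               survey_loglik(counts, svy))
})

test_that("dataset constructors validate and map against grids", {
  g <- tiny_grid()
  ds <- survey_dataset(tibble::tibble(
    age = c("a1", "a2", "a1"), sex = c("F", "F", "M"),
    year = c(2000, 2001, 2002), value = 1:3, sd = 1),
    aggregate = c("region", "urban"))
  map <- prevfuse:::dataset_cell_map(ds, g)
  expect_equal(length(map$cell_index), 3)
  dup <- survey_dataset(tibble::tibble(
    age = c("a1", "a1"), sex = "F", year = 2000, value = 1:2, sd = 1),
    aggregate = c("region", "urban"))
  expect_error(prevfuse:::dataset_cell_map(dup, g), "duplicated")
  bad <- survey_dataset(tibble::tibble(
    age = "zz", sex = "F", year = 2000, value = 1, sd = 1),
    aggregate = c("region", "urban"))
  expect_error(prevfuse:::dataset_cell_map(bad, g), "zz")
  expect_error(survey_dataset(tibble::tibble(age = "a1", value = 1)),
               "sd")
  expect_error(admin_dataset(tibble::tibble(age = "a1", value = 0)),
               "positive")
  expect_error(binomial_dataset(tibble::tibble(y_eff = 5, n_eff = 3)),
               "y_eff")
})
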