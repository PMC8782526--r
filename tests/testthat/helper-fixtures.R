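# Small fixtures shared across test files. Everything is generated in
# code; fits are cached per session because several test files probe the
# same small posterior.

tiny_grid <- function(years = 2000:2005, data_until = max(years)) {
  prev_grid(ages = c("a1", "a2"), sexes = c("F", "M"), years = years,
            data_until = data_until)
}

# national-style grid with a forecast horizon
toy_grid <- function() {
  prev_grid(ages = c("a1", "a2"), sexes = c("F", "M"),
            years = 2000:2014, data_until = 2009)
}

# a small, quick scenario used by sampler and checking tests: 2 ages x
# 2 sexes x 2 regions, 16 observed + 4 forecast years
toy_scenario <- function() {
  prev_scenario(
    ages = c("a1", "a2"), sexes = c("F", "M"),
    regions = c("r1", "r2"), urban = "all",
    years = 1998:2017, data_until = 2013,
    age_effects = c(-0.2, 0.2), sex_effects = c(-0.1, 0.1),
    urban_effects = 0, region_sd = 0.15,
    age_drifts = c(0, 0.02),
    gamma = c(0, -0.4),
    survey_years = c(1999, 2003, 2007, 2011),
    survey_omit = list(),
    admin_years = 2009:2013,
    n_true_per_cell = 5e4,
    panel_countries = 12, panel_years = 1998:2013
  )
}

.fixture_env <- new.env(parent = emptyenv())

# one cached multi-source fit on the toy scenario, reused by summary,
# checking and tidier tests
toy_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  sc <- toy_scenario()
  bundle <- simulate_bundle(sc, seed = 31)
  tr <- bundle$truth
  so <- bundle$sources
  fit <- suppressWarnings(prev_fit(
    tr$grid, default_terms(tr$grid),
    datasets = list(so$survey, so$admin),
    exposures = so$exposures,
    config = prev_config(chains = 2, warmup = 300, iter = 300, seed = 5)
  ))
  .fixture_env$fit <- fit
  .fixture_env$truth <- tr
  .fixture_env$scenario <- sc
  fit
}

toy_truth <- function() {
  toy_fit()
  .fixture_env$truth
}

# National-level views of a subnational bundle: the sparse survey as
# effective counts (single-source binomial path), the same survey as a
# normal data model, and the admin source aggregated over region and
# urban. Used for the forecast-width comparisons.
national_views <- function(bundle, scenario) {
  tr <- bundle$truth
  so <- bundle$sources
  g_nat <- prev_grid(ages = scenario$ages, sexes = scenario$sexes,
                     years = scenario$years,
                     data_until = scenario$data_until)
  n_sub <- length(scenario$regions) * length(scenario$urban)
  n_agg <- scenario$n_true_per_cell * n_sub
  svy <- so$survey$data
  p_hat <- pmin(pmax(svy$value / n_agg, 1e-4), 1 - 1e-4)
  ec <- effective_counts(p_hat, (svy$sd / n_agg)^2)
  bin <- binomial_dataset(dplyr::bind_cols(
    svy[, c("age", "sex", "year")],
    tibble::tibble(region = "all", urban = "all"), ec), name = "survey_ec")
  adm_nat <- dplyr::summarise(
    dplyr::group_by(so$admin$data, .data$age, .data$sex, .data$year),
    value = sum(.data$value), .groups = "drop")
  adm_nat$region <- "all"
  adm_nat$urban <- "all"
  expo_nat <- dplyr::mutate(
    grid_cells(g_nat)[, c("age", "sex", "region", "urban", "year")],
    n_true = n_agg)
  list(grid = g_nat,
       binomial_survey = bin,
       survey = survey_dataset(svy, aggregate = c("region", "urban")),
       extra_survey = so$extra_survey,
       admin = admin_dataset(adm_nat, name = "admin"),
       exposures = expo_nat)
}

# mean width of the 95% interval at the last forecast year
horizon_width <- function(fit) {
  sm <- summarise_prevalence(fit)
  last <- sm[sm$year == max(sm$year), ]
  mean(last$upper_95 - last$lower_95)
}
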