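#' Synthetic-data scenarios
#'
#' A scenario bundles everything needed to generate a complete synthetic
#' input set with the statistical structure the analysis assumes: the
#' classification grid, true effect patterns and trend hyperparameters,
#' known exposures, and the designs of the observed sources — a sparse
#' national survey with round-specific age gaps, a single-round
#' sex-aggregated survey covering the youngest age only, a dense
#' administrative source for a late subperiod with an age-varying
#' multiplicative bias and log-scale noise, and a smooth international
#' panel of prevalence estimates with 95% intervals.
#'
#' Defaults mirror the study conditions: 4 age groups x 2 sexes x
#' 8 regions x urban/rural, years 1990-2029 with data to 2019 (a 10-year
#' forecast horizon); survey rounds in 1991, 1997, 2004, 2009 and 2014
#' with the 2004 round omitting the two youngest age groups; an
#' administrative source for 2013-2019 whose bias is near zero for the
#' youngest age group and substantially negative for the others; exposures
#' of 1e5 children per cell; and a 40-country panel for 1990-2016.
#'
#' @param ages,sexes,regions,urban,years,data_until Grid layout.
#' @param intercept,age_effects,sex_effects,urban_effects Fixed true
#'   effects (age/sex/urban given as per-level values, centred
#'   internally).
#' @param region_sd Spread of the exchangeable true region effects.
#' @param sigma Cell-level logit-scale noise sd of true prevalence.
#' @param time_hypers,age_time_hypers,sex_time_hypers True
#'   [trend_hypers()] for the year main effect and interactions.
#' @param time_init Named vector `c(level, drift)` at time 0 for the year
#'   main effect.
#' @param age_drifts Initial per-age drifts of the age-year interaction
#'   (older ages rising faster, as in the motivating data).
#' @param n_true_per_cell Known exposure per cell.
#' @param survey_years,survey_omit,survey_sample_size National survey
#'   rounds, a named list of age groups omitted per round, and the
#'   effective per-cell sample size driving kappa.
#' @param extra_survey_year,extra_survey_ages,extra_survey_sample_size The
#'   single-round sex-aggregated source.
#' @param admin_years,gamma,sigma_y Administrative subperiod, true
#'   age-bias vector (log scale), and log-scale noise sd.
#' @param panel_countries,panel_years,panel_n_eff,panel_time_hypers,
#'   panel_sigma,panel_country_sd International panel design.
#' @return A list of class `prev_scenario`.
#' @export
prev_scenario <- function(
    ages = c("2-4", "5-9", "10-14", "15-17"),
    sexes = c("female", "male"),
    regions = paste0("region_", 1:8),
    urban = c("urban", "rural"),
    years = 1990:2029,
    data_until = 2019,
    intercept = -2.3,
    age_effects = c(-0.25, -0.05, 0.1, 0.2),
    sex_effects = c(-0.1, 0.1),
    region_sd = 0.15,
    urban_effects = c(0.1, -0.1),
    sigma = 0.1,
    time_hypers = trend_hypers(0.005, 0.01, 0.02, 0.9),
    time_init = c(level = 0, drift = 0.04),
    age_time_hypers = trend_hypers(0.005, 0.005, 0.01, 0.9),
    age_drifts = c(-0.02, 0, 0.01, 0.02),
    sex_time_hypers = trend_hypers(0.005, 0.005, 0.01, 0.9),
    n_true_per_cell = 1e5,
    survey_years = c(1991, 1997, 2004, 2009, 2014),
    survey_omit = list("2004" = c("2-4", "5-9")),
    survey_sample_size = 400,
    extra_survey_year = 2001,
    extra_survey_ages = "2-4",
    extra_survey_sample_size = 2000,
    admin_years = 2013:2019,
    gamma = c(0, -0.35, -0.5, -0.5),
    sigma_y = 0.1,
    panel_countries = 40,
    panel_years = 1990:2016,
    panel_n_eff = 5000,
    panel_time_hypers = trend_hypers(0.005, 0.01, 0.015, 0.9),
    panel_sigma = 0.02,
    panel_country_sd = 0.5) {
  stopifnot(all(survey_years %in% years), all(admin_years %in% years),
            all(survey_years <= data_until), all(admin_years <= data_until),
            length(gamma) == length(ages),
            length(age_effects) == length(ages),
            length(age_drifts) == length(ages),
            sigma > 0, sigma_y > 0, n_true_per_cell > 0)
  spec <- as.list(environment())
  structure(spec, class = "prev_scenario")
}

#' Generate ground truth from a scenario
#'
#' Builds the grid and draws the full latent state in the generative
#' direction: fixed (centred) main effects, exchangeable region effects,
#' damped-trend time effects simulated from the scenario's true
#' hyperparameters, logit-normal prevalences, and binomial true counts.
#' Everything is recorded so recovery can be checked.
#'
#' @param scenario A [prev_scenario()].
#' @param seed Integer seed.
#' @return A list of class `prev_truth`: `grid`, `effects`, `theta`,
#'   `pi`, `counts` (tibble with `y_true`, `n_true`), `hypers`, `seed`.
#' @export
generate_truth <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "prev_scenario"))
  sc <- scenario
  set.seed(seed)
  grid <- prev_grid(sc$ages, sc$sexes, sc$regions, sc$urban, sc$years,
                    sc$data_until)
  terms <- default_terms(grid)
  design <- build_design(terms, grid)
  nT <- length(sc$years)
  ctr <- function(x) x - mean(x)
  tr_time <- simulate_damped_trend(sc$time_hypers,
                                   init_level = sc$time_init[["level"]],
                                   init_drift = sc$time_init[["drift"]],
                                   n_time = nT)
  age_tr <- purrr::map(sc$age_drifts, function(d0) {
    simulate_damped_trend(sc$age_time_hypers, 0, d0, nT)$beta
  })
  nA <- length(sc$ages)
  age_year <- as.vector(t(matrix(unlist(age_tr), nT, nA,
                                 dimnames = NULL))) # chain-fastest layout
  sex_tr <- purrr::map(seq_along(sc$sexes), function(i) {
    simulate_damped_trend(sc$sex_time_hypers, 0,
                          c(-0.005, 0.005)[i], nT)$beta
  })
  sex_year <- as.vector(t(matrix(unlist(sex_tr), nT, length(sc$sexes))))
  effects <- list(
    "(Intercept)" = sc$intercept,
    age = ctr(sc$age_effects),
    sex = ctr(sc$sex_effects),
    region = ctr(stats::rnorm(length(sc$regions), 0, sc$region_sd)),
    urban = ctr(sc$urban_effects),
    year = tr_time$beta,
    "age:sex" = rep(0, nA * length(sc$sexes)),
    "age:year" = age_year,
    "sex:year" = sex_year
  )
  mu <- linear_predictor(effects, design)
  theta <- stats::rnorm(length(mu), mu, sc$sigma)
  pi <- inv_logit(theta)
  cells <- grid_cells(grid)
  n_true <- rep(as.integer(sc$n_true_per_cell), nrow(cells))
  y_true <- stats::rbinom(nrow(cells), n_true, pi)
  counts <- dplyr::mutate(cells, n_true = n_true, y_true = y_true)
  structure(
    list(grid = grid, terms = terms, effects = effects, theta = theta,
         pi = pi, counts = counts,
         hypers = list(sigma = sc$sigma, time = sc$time_hypers,
                       age_time = sc$age_time_hypers,
                       sex_time = sc$sex_time_hypers, gamma = sc$gamma,
                       sigma_y = sc$sigma_y),
         seed = seed),
    class = "prev_truth"
  )
}

#' Generate the observed data sources from a truth bundle
#'
#' Applies each data model in the generative direction: the national
#' survey source observes sex-region-urban-aggregated true counts through
#' unbiased normal noise with known design-based sds (kappa derived from
#' the scenario's effective sample sizes); the single-round source is
#' additionally sex-aggregated; the administrative source observes every
#' cell of the late subperiod through the log-scale model with its
#' age-specific bias; and the panel source is simulated from the
#' country-panel model and reported as point estimates with 95% intervals.
#' Coverage gaps in the scenario are honoured via missing rows.
#'
#' @param truth Output of [generate_truth()].
#' @param scenario The same [prev_scenario()].
#' @param seed Integer seed (independent of the truth seed).
#' @return A list of class `prev_sources`: `survey`, `extra_survey`,
#'   `admin` (datasets), `panel` (tibble), `exposures` (tibble).
#' @export
generate_sources <- function(truth, scenario, seed = 2) {
  stopifnot(inherits(truth, "prev_truth"), inherits(scenario, "prev_scenario"))
  sc <- scenario
  set.seed(seed)
  counts <- truth$counts

  # national survey: aggregated over region & urban
  agg <- dplyr::summarise(
    dplyr::group_by(counts, .data$age, .data$sex, .data$year),
    y_true = sum(.data$y_true), n_true = sum(.data$n_true),
    .groups = "drop")
  svy <- dplyr::filter(agg, .data$year %in% sc$survey_years)
  omit <- purrr::imap_dfr(sc$survey_omit, function(ages, yr) {
    tibble::tibble(year = as.integer(yr), age = ages)
  })
  if (nrow(omit)) {
    svy <- dplyr::anti_join(svy, omit, by = c("year", "age"))
  }
  p_agg <- svy$y_true / svy$n_true
  kappa <- svy$n_true * sqrt(p_agg * (1 - p_agg) / sc$survey_sample_size)
  svy_out <- tibble::tibble(
    age = svy$age, sex = svy$sex, year = svy$year,
    value = stats::rnorm(nrow(svy), svy$y_true, kappa),
    sd = kappa
  )

  # single-round sex-aggregated source
  agg2 <- dplyr::summarise(
    dplyr::group_by(counts, .data$age, .data$year),
    y_true = sum(.data$y_true), n_true = sum(.data$n_true),
    .groups = "drop")
  ex <- dplyr::filter(agg2, .data$year == sc$extra_survey_year,
                      .data$age %in% sc$extra_survey_ages)
  p2 <- ex$y_true / ex$n_true
  kappa2 <- ex$n_true * sqrt(p2 * (1 - p2) / sc$extra_survey_sample_size)
  ex_out <- tibble::tibble(
    age = ex$age, year = ex$year,
    value = stats::rnorm(nrow(ex), ex$y_true, kappa2),
    sd = kappa2
  )

  # administrative source: full classification, late subperiod
  adm <- dplyr::filter(counts, .data$year %in% sc$admin_years)
  gam <- stats::setNames(sc$gamma, sc$ages)
  adm_out <- tibble::tibble(
    age = adm$age, sex = adm$sex, region = adm$region, urban = adm$urban,
    year = adm$year,
    value = exp(log(pmax(adm$y_true, 0.5)) + gam[adm$age] +
                  stats::rnorm(nrow(adm), 0, sc$sigma_y))
  )

  # international panel
  panel <- simulate_panel(sc)

  exposures <- dplyr::select(counts, dplyr::all_of(names(truth$grid$dims)),
                             "n_true")
  structure(
    list(
      survey = survey_dataset(svy_out, aggregate = c("region", "urban"),
                              name = "survey"),
      extra_survey = survey_dataset(ex_out,
                                    aggregate = c("region", "urban", "sex"),
                                    name = "extra_survey"),
      admin = admin_dataset(adm_out, name = "admin"),
      panel = panel,
      exposures = exposures
    ),
    class = "prev_sources"
  )
}

# country-by-sex-by-year panel simulated from the panel model structure
simulate_panel <- function(sc) {
  countries <- sprintf("country_%02d", seq_len(sc$panel_countries))
  sexes <- sc$sexes
  nT <- length(sc$panel_years)
  tr <- simulate_damped_trend(sc$panel_time_hypers, 0, 0.03, nT)
  b_ctry <- stats::rnorm(length(countries), 0, sc$panel_country_sd)
  b_sex <- c(-0.1, 0.1)[seq_along(sexes)]
  b_cs <- matrix(stats::rnorm(length(countries) * length(sexes), 0, 0.2),
                 length(countries))
  g <- tidyr::expand_grid(country = countries, sex = sexes,
                          year = sc$panel_years)
  mu <- -2 + b_ctry[match(g$country, countries)] +
    b_sex[match(g$sex, sexes)] +
    b_cs[cbind(match(g$country, countries), match(g$sex, sexes))] +
    tr$beta[match(g$year, sc$panel_years)]
  pi <- inv_logit(stats::rnorm(nrow(g), mu, sc$panel_sigma))
  y <- stats::rbinom(nrow(g), sc$panel_n_eff, pi)
  p_hat <- pmin(pmax(y / sc$panel_n_eff, 1e-4), 1 - 1e-4)
  se <- sqrt(p_hat * (1 - p_hat) / sc$panel_n_eff)
  dplyr::mutate(g, estimate = p_hat,
                lower = pmax(p_hat - 1.96 * se, 1e-6),
                upper = pmin(p_hat + 1.96 * se, 1 - 1e-6))
}

#' Generate a complete synthetic input bundle
#'
#' @param scenario A [prev_scenario()].
#' @param seed Master seed; truth and sources use seeds derived from it.
#' @return A list with `truth` and `sources`.
#' @export
simulate_bundle <- function(scenario = prev_scenario(), seed = 1) {
  truth <- generate_truth(scenario, seed = seed)
  sources <- generate_sources(truth, scenario, seed = seed + 1000L)
  list(truth = truth, sources = sources)
}
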