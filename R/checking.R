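#' Replicate-data generation
#'
#' Generates one hypothetical administrative dataset from the fitted
#' model, following the four-step recipe: take the effect vector and
#' cell-level noise sd from posterior draw `k`; draw fresh
#' logit-prevalences from the prior model given those values; draw true
#' counts from the binomial count layer; and draw administrative
#' estimates from the administrative data model given the drawn bias and
#' noise parameters. The replicate carries exactly the observation mask of
#' the fitted administrative source, and is reproducible given `(k,
#' seed)`.
#'
#' @param fit A `prev_fit` whose datasets include an admin source.
#' @param k Pooled posterior draw index.
#' @param seed Integer seed.
#' @return A tibble shaped like the admin data (classification columns
#'   plus `value`), with attributes `draw` (k) and `seed`.
#' @export
generate_replicate <- function(fit, k, seed = 1) {
  stopifnot(inherits(fit, "prev_fit"))
  su <- fit$setup
  if (!length(su$admin)) {
    stop("fit has no administrative dataset to replicate", call. = FALSE)
  }
  dr <- posterior_draw(fit, k)
  set.seed(seed)
  mu <- linear_predictor(dr$effects, fit$design)
  theta_rep <- stats::rnorm(length(mu), mu, dr$sigma)
  pi_rep <- inv_logit(theta_rep)
  dsn <- names(su$admin)[1]
  a <- su$admin[[dsn]]
  n <- su$n_true[a$cell]
  y_rep <- stats::rbinom(length(a$cell), n, pi_rep[a$cell])
  y_rep <- pmax(y_rep, 0.5) # continuity guard: log of the count is taken
  gamma <- dr$gamma[[dsn]]
  sy <- dr$sigma_y[[dsn]]
  value <- exp(log(y_rep) + gamma[a$age_idx] +
                 stats::rnorm(length(y_rep), 0, sy))
  ds <- purrr::keep(fit$datasets, ~ .x$kind == "admin")[[1]]
  out <- dplyr::mutate(
    dplyr::select(ds$data, -dplyr::all_of("value")), value = value)
  attr(out, "draw") <- k
  attr(out, "seed") <- seed
  out
}

#' Per-series least-squares slopes
#'
#' For each combination of the non-time classification columns, the
#' ordinary least-squares slope of `value` against `year`: the summary
#' measure used to compare observed and replicate administrative datasets.
#' Series with fewer than two time points are skipped with a warning.
#'
#' @param data Tibble with classification columns, `year`, and `value`.
#' @return A tibble of the grouping columns plus `slope`.
#' @export
slope_summaries <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("year", "value") %in% names(data)))
  keys <- setdiff(names(data), c("year", "value"))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    grouped,
    n_points = dplyr::n(),
    slope = if (dplyr::n() >= 2) {
      stats::cov(.data$year, .data$value) / stats::var(.data$year)
    } else NA_real_,
    .groups = "drop")
  if (any(out$n_points < 2)) {
    warning(sum(out$n_points < 2),
            " series with a single time point skipped")
    out <- dplyr::filter(out, .data$n_points >= 2)
  }
  dplyr::select(out, -dplyr::all_of("n_points"))
}

#' Replicate-data check of geographical trend variation
#'
#' Generates `K` replicate administrative datasets from the fitted model,
#' summarises each series (age-sex-region-urban combination) by its
#' least-squares slope against time, and compares the observed slopes with
#' the replicate distribution. A series is flagged when its observed slope
#' is more extreme than all `K` replicates in either direction, so under a
#' well-specified model each series is flagged with probability
#' `2 / (K + 1)` — exactly 5% at the default `K = 39`. The verdict
#' compares the flagged fraction with that expectation.
#'
#' @param fit A `prev_fit` with an admin dataset.
#' @param K Number of replicate datasets (>= 2; a warning is issued below
#'   19 because rank resolution becomes very coarse).
#' @param seed Integer seed (replicate j uses `seed + j`).
#' @param observed Optional tibble to treat as the observed administrative
#'   dataset instead of the one the model was fitted to (same columns);
#'   used for self-consistency checks where the "observed" data are
#'   themselves a model replicate.
#' @return A list of class `replicate_check`: `series` (tibble with
#'   observed slope, replicate rank, and `flagged`), `flagged_fraction`,
#'   `expected_fraction`, `K`, and `outlier` (TRUE when the flagged
#'   fraction exceeds the upper 95% binomial bound of the expectation).
#' @export
replicate_check <- function(fit, K = 39, seed = 1, observed = NULL) {
  stopifnot(inherits(fit, "prev_fit"), K >= 2)
  if (K < 19) {
    warning("K < 19 gives very coarse rank granularity")
  }
  ds <- purrr::keep(fit$datasets, ~ .x$kind == "admin")
  if (!length(ds)) stop("fit has no administrative dataset", call. = FALSE)
  if (is.null(observed)) observed <- ds[[1]]$data
  obs <- slope_summaries(observed)
  n_draws <- sum(vapply(fit$chains, function(ch) nrow(ch$hyper), 1L))
  set.seed(seed)
  ks <- sample.int(n_draws, K, replace = K > n_draws)
  reps <- purrr::imap(ks, function(k, j) {
    slope_summaries(generate_replicate(fit, k, seed = seed + j))$slope
  })
  repmat <- do.call(cbind, reps) # series x K
  keys <- setdiff(names(obs), "slope")
  rank_obs <- rowSums(repmat < obs$slope) + 1L
  flagged <- obs$slope < apply(repmat, 1, min) |
    obs$slope > apply(repmat, 1, max)
  series <- dplyr::mutate(obs, rank = rank_obs, flagged = flagged)
  n <- nrow(series)
  expected <- 2 / (K + 1)
  upper <- stats::qbinom(0.975, n, expected) / n
  structure(
    list(series = series, flagged_fraction = mean(flagged),
         expected_fraction = expected, K = K, n_series = n,
         outlier = mean(flagged) > upper),
    class = "replicate_check"
  )
}

#' @export
print.replicate_check <- function(x, ...) {
  cat("<replicate_check> ", x$n_series, " series vs ", x$K,
      " replicates\n  flagged ", round(100 * x$flagged_fraction, 1),
      "% (expected ", round(100 * x$expected_fraction, 1), "%) -> ",
      if (x$outlier) "observed data look like an OUTLIER" else
        "observed data are not an outlier", "\n", sep = "")
  invisible(x)
}

#' Sensitivity grid over model and prior variants
#'
#' Fits every combination of a dataset configuration ("model variant")
#' and a time-prior specification, and returns the aggregate national
#' prevalence summaries for each, enabling row-by-column comparisons of
#' how stronger trend priors tighten forecasts under each model. Failures
#' of individual fits are recorded and do not abort the grid.
#'
#' @param grid A [prev_grid()].
#' @param model_variants Named list; each element a list of datasets.
#' @param prior_variants Named list of [prior_damped_trend()] objects
#'   applied to all three time terms.
#' @param exposures,priors,config Passed to [prev_fit()].
#' @return A tibble with columns `model`, `prior`, `summaries` (nested
#'   [aggregate_prevalence()] tables), `fit` (nested), `error`.
#' @export
sensitivity_grid <- function(grid, model_variants, prior_variants,
                             exposures = NULL, priors = fit_priors(),
                             config = prev_config()) {
  stopifnot(length(model_variants) >= 1, length(prior_variants) >= 1)
  combos <- tidyr::expand_grid(model = names(model_variants),
                               prior = names(prior_variants))
  res <- purrr::pmap(combos, function(model, prior) {
    tp <- prior_variants[[prior]]
    out <- tryCatch({
      fit <- prev_fit(grid, default_terms(grid, time_prior = tp),
                      datasets = model_variants[[model]],
                      priors = priors, exposures = exposures,
                      config = config)
      list(summaries = aggregate_prevalence(fit), fit = fit,
           error = NA_character_)
    }, error = function(e) {
      list(summaries = NULL, fit = NULL, error = conditionMessage(e))
    })
    out
  })
  dplyr::mutate(combos,
                summaries = purrr::map(res, "summaries"),
                fit = purrr::map(res, "fit"),
                error = purrr::map_chr(res, "error"))
}
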