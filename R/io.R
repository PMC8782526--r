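#' Read datasets from CSV
#'
#' CSV schemas: one column per classification dimension the source
#' observes, plus `value` and (surveys) `sd`; the panel reader expects
#' `country, sex, year, estimate, lower, upper`. Labels are validated
#' against the grid (errors name the row and column), duplicate cells are
#' an error, and row order is irrelevant.
#'
#' @param path CSV file path.
#' @param grid The grid to validate against.
#' @param aggregate Dimensions the survey source aggregates over.
#' @param name Dataset label.
#' @return A `prev_dataset` (or, for the panel, a validated tibble).
#' @export
read_survey_csv <- function(path, grid, aggregate = character(),
                            name = "survey") {
  ds <- survey_dataset(read_csv_strict(path), aggregate = aggregate,
                       name = name)
  dataset_cell_map(ds, grid)
  ds
}

#' @rdname read_survey_csv
#' @export
read_admin_csv <- function(path, grid, name = "admin") {
  ds <- admin_dataset(read_csv_strict(path), name = name)
  dataset_cell_map(ds, grid)
  ds
}

#' @rdname read_survey_csv
#' @export
read_panel_csv <- function(path) {
  d <- read_csv_strict(path)
  need <- c("country", "sex", "year", "estimate", "lower", "upper")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("panel CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(d$country, d$sex, d$year)
  if (anyDuplicated(key) > 0) {
    stop("duplicated (country, sex, year) row in panel CSV", call. = FALSE)
  }
  d
}

#' @rdname read_survey_csv
#' @export
read_exposures_csv <- function(path, grid) {
  d <- read_csv_strict(path)
  if (!"n_true" %in% names(d)) {
    stop("exposures CSV needs an `n_true` column", call. = FALSE)
  }
  cells_from_labels(grid, d) # validates labels
  d
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and re-read summary tables
#'
#' Summary tables are stored long: one row per (cell, quantile), with a
#' numeric `quantile` column (0.5 for the median, 0.025/0.975 for the 95%
#' interval, and so on), re-readable losslessly to full double precision.
#'
#' @param summaries Wide summary tibble from [summarise_prevalence()].
#' @param path Output CSV path.
#' @export
write_summaries <- function(summaries, path) {
  valcols <- grep("^(median|lower_|upper_)", names(summaries), value = TRUE)
  long <- tidyr::pivot_longer(summaries, dplyr::all_of(valcols),
                              names_to = "which", values_to = "value")
  long$quantile <- vapply(long$which, function(w) {
    if (w == "median") return(0.5)
    lev <- as.numeric(sub("^(lower|upper)_", "", w)) / 100
    if (startsWith(w, "lower")) (1 - lev) / 2 else 1 - (1 - lev) / 2
  }, numeric(1))
  long$which <- NULL
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  long <- read_csv_strict(path)
  long$which <- vapply(long$quantile, function(q) {
    if (q == 0.5) return("median")
    lev <- round(100 * abs(1 - 2 * q))
    if (q < 0.5) paste0("lower_", lev) else paste0("upper_", lev)
  }, character(1))
  long$quantile <- NULL
  tidyr::pivot_wider(long, names_from = "which", values_from = "value")
}

#' Run configuration files
#'
#' A YAML run configuration declares the grid, the time-prior choice, and
#' the MCMC settings:
#' ```yaml
#' grid:
#'   ages: ["2-4", "5-9"]
#'   sexes: [female, male]
#'   regions: [all]        # optional, default singleton
#'   urban: [all]          # optional
#'   years: {from: 1990, to: 2029}
#'   data_until: 2019
#' time_prior:             # optional; default weakly informative
#'   tau_beta_sd: 0.0054
#'   tau_alpha_sd: 0.01
#'   tau_delta_sd: 0.02
#'   phi_a: 2.0
#'   phi_b: 2.0
#' fit: {chains: 4, warmup: 1000, iter: 1000, seed: 1}
#' ```
#' Configurations round-trip unchanged through
#' `write_run_config()`/`read_run_config()`.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a list with `grid` (a [prev_grid()]),
#'   `terms`, `config` (a [prev_config()]), and the `raw` parsed list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  g <- raw$grid
  if (is.null(g)) stop("config lacks a `grid` block", call. = FALSE)
  grid <- prev_grid(
    ages = g$ages, sexes = g$sexes,
    regions = g$regions %||% "all", urban = g$urban %||% "all",
    years = seq(g$years$from, g$years$to),
    data_until = g$data_until %||% g$years$to
  )
  tp <- raw$time_prior
  time_prior <- if (is.null(tp)) {
    prior_damped_trend()
  } else {
    prior_damped_trend(
      tau_beta = prior_half_normal(tp$tau_beta_sd %||% 1),
      tau_alpha = prior_half_normal(tp$tau_alpha_sd %||% 1),
      tau_delta = prior_half_normal(tp$tau_delta_sd %||% 1),
      phi = prior_scaled_beta(tp$phi_a %||% 2, tp$phi_b %||% 2, 0.8, 1)
    )
  }
  f <- raw$fit %||% list()
  config <- prev_config(chains = f$chains %||% 4,
                        warmup = f$warmup %||% 1000,
                        iter = f$iter %||% 1000,
                        seed = f$seed %||% 1)
  list(grid = grid, terms = default_terms(grid, time_prior = time_prior),
       config = config, raw = raw)
}

#' @rdname read_run_config
#' @param raw The parsed configuration list to serialise.
#' @export
write_run_config <- function(raw, path) {
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run metadata for provenance logging
#'
#' Records the package version, seed, a hash of the configuration, and
#' content hashes of input files; written alongside outputs so a run can
#' be traced.
#'
#' @param seed Integer seed of the run.
#' @param config Any configuration object.
#' @param files Character vector of input file paths.
#' @param path Optional JSON output path.
#' @return A list (invisibly written to `path` when given).
#' @export
run_metadata <- function(seed, config = NULL, files = character(),
                         path = NULL) {
  meta <- list(
    package = "prevfuse",
    version = as.character(utils::packageVersion("prevfuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = rlang::hash(config),
    input_hashes = as.list(stats::setNames(
      unname(tools::md5sum(files[file.exists(files)])),
      files[file.exists(files)]))
  )
  if (!is.null(path)) {
    jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(meta)
}

#' Write a synthetic bundle to CSV
#'
#' Writes the survey, extra-survey, admin, panel, and exposure tables of a
#' [simulate_bundle()] result to a directory, plus a ground-truth JSON
#' with the scenario hyperparameters.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle_csv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$sources$survey$data, file.path(dir, "survey.csv"))
  readr::write_csv(bundle$sources$extra_survey$data,
                   file.path(dir, "extra_survey.csv"))
  readr::write_csv(bundle$sources$admin$data, file.path(dir, "admin.csv"))
  readr::write_csv(bundle$sources$panel, file.path(dir, "panel.csv"))
  readr::write_csv(bundle$sources$exposures, file.path(dir, "exposures.csv"))
  tr <- bundle$truth
  truth_json <- list(
    seed = tr$seed, sigma = tr$hypers$sigma,
    gamma = tr$hypers$gamma, sigma_y = tr$hypers$sigma_y,
    time = unclass(tr$hypers$time)[c("tau_beta", "tau_alpha", "tau_delta",
                                     "phi")]
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
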