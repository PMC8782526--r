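#' Observed datasets and their data models
#'
#' Each observed dataset is a tibble of per-cell records plus a declared
#' data model relating it to the latent true counts:
#'
#' * `survey_dataset()` — design-based survey estimates of case counts with
#'   known standard deviations, modelled as unbiased normal:
#'   `value ~ N(sum of true counts over the aggregated dimensions, sd^2)`.
#'   The `aggregate` argument names grid dimensions summed out of the true
#'   counts before comparison (e.g. region and urban for a national survey
#'   fed to a subnational model; additionally sex for a source that does
#'   not record sex).
#' * `binomial_dataset()` — effective counts fitted directly with a
#'   (continuously extended) binomial likelihood on the cell prevalence;
#'   used when a single survey source is modelled without a separate
#'   measurement layer, and for the international panel model.
#' * `admin_dataset()` — administrative case counts observed on the full
#'   classification for a contiguous late subperiod, modelled on the log
#'   scale with an age-specific multiplicative bias:
#'   `log(value) ~ N(log(y_true) + gamma_age, sigma_y^2)`,
#'   `gamma_age ~ N(0, sigma_gamma^2)`.
#'
#' Missing cells are encoded by absence of a row (an explicit observation
#' mask is derived at fit time), never by sentinel values.
#'
#' @param data A tibble. Dimension columns must match the grid labels; in
#'   addition `survey_dataset()` needs `value` and `sd`, `admin_dataset()`
#'   needs a positive `value`, and `binomial_dataset()` needs `y_eff` and
#'   `n_eff`.
#' @param aggregate Character vector of grid dimensions summed out before
#'   comparison (may be empty).
#' @param name Optional label used in printed output.
#' @return A `prev_dataset` object (list with `kind`, `data`, `aggregate`,
#'   `name`).
#' @export
survey_dataset <- function(data, aggregate = character(), name = "survey") {
  data <- tibble::as_tibble(data)
  req <- c("value", "sd")
  if (!all(req %in% names(data))) {
    stop("survey data needs columns `value` and `sd`", call. = FALSE)
  }
  if (any(!is.finite(data$sd)) || any(data$sd <= 0)) {
    stop("survey `sd` must be positive wherever observed", call. = FALSE)
  }
  new_dataset("survey", data, aggregate, name)
}

#' @rdname survey_dataset
#' @export
binomial_dataset <- function(data, name = "survey") {
  data <- tibble::as_tibble(data)
  if (!all(c("y_eff", "n_eff") %in% names(data))) {
    stop("binomial data needs columns `y_eff` and `n_eff`", call. = FALSE)
  }
  if (any(data$n_eff <= 0) || any(data$y_eff < 0 | data$y_eff > data$n_eff)) {
    stop("need 0 <= y_eff <= n_eff and n_eff > 0", call. = FALSE)
  }
  new_dataset("binomial", data, character(), name)
}

#' @rdname survey_dataset
#' @export
admin_dataset <- function(data, name = "admin") {
  data <- tibble::as_tibble(data)
  if (!"value" %in% names(data)) {
    stop("admin data needs a `value` column", call. = FALSE)
  }
  if (any(data$value <= 0)) {
    stop("admin `value` must be positive (its log is modelled)",
         call. = FALSE)
  }
  new_dataset("admin", data, character(), name)
}

new_dataset <- function(kind, data, aggregate, name) {
  structure(list(kind = kind, data = data, aggregate = as.character(aggregate),
                 name = name),
            class = "prev_dataset")
}

#' @export
print.prev_dataset <- function(x, ...) {
  cat("<prev_dataset:", x$kind, "> '", x$name, "', ", nrow(x$data),
      " observed cells", sep = "")
  if (length(x$aggregate)) {
    cat(", aggregates over ", paste(x$aggregate, collapse = "+"), sep = "")
  }
  cat("\n")
  invisible(x)
}

# Validate a dataset against a grid: label checks, duplicate checks, and
# the cell map (for each observation row, the grid cell indices it sums
# over). Observation dims = grid dims minus `aggregate`.
dataset_cell_map <- function(ds, grid) {
  obs_dims <- setdiff(names(grid$dims), ds$aggregate)
  missing <- setdiff(obs_dims, names(ds$data))
  if (length(missing)) {
    stop("dataset '", ds$name, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(ds$data[obs_dims], sep = "\r"))
  if (anyDuplicated(key) > 0) {
    stop("dataset '", ds$name, "' has duplicated cells (row ",
         which(duplicated(key))[1], ")", call. = FALSE)
  }
  for (nm in obs_dims) {
    m <- match(as.character(ds$data[[nm]]), as.character(grid$dims[[nm]]))
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop("dataset '", ds$name, "': unknown label `", ds$data[[nm]][bad],
           "` in column `", nm, "` (row ", bad, ")", call. = FALSE)
    }
  }
  if (any(ds$data$year > grid$data_until)) {
    stop("dataset '", ds$name, "' has observations beyond the observed span",
         call. = FALSE)
  }
  cells <- grid_cells(grid)
  joined <- dplyr::left_join(
    dplyr::mutate(ds$data, .obs = dplyr::row_number()),
    cells,
    by = stats::setNames(obs_dims, obs_dims)
  )
  # one row per (observation, contributing grid cell)
  list(obs_dims = obs_dims,
       obs_index = joined$.obs,
       cell_index = joined$cell)
}

# ---- likelihood operations ----------------------------------------------

#' Effective counts from a design-based proportion estimate
#'
#' Converts a complex-survey proportion estimate and its design-based
#' variance into pseudo-counts `(y_eff, n_eff)` that reproduce the same
#' mean and variance under a simple-random-sampling working model:
#' `n_eff = p_hat (1 - p_hat) / var_p_hat`, `y_eff = p_hat * n_eff`. The
#' effective sample size is the raw size divided by the design effect.
#'
#' @param p_hat Estimated proportion(s), strictly inside (0, 1). Boundary
#'   estimates must first be clamped to `[1/(2 n_raw), 1 - 1/(2 n_raw)]`
#'   using the known raw sample size (see `clamp_proportion()`).
#' @param var_p_hat Design-based variance(s) of `p_hat` (> 0).
#' @return A tibble with columns `y_eff`, `n_eff`.
#' @examples
#' effective_counts(0.3, 0.3 * 0.7 / 200) # n_eff = 200, y_eff = 60
#' @export
effective_counts <- function(p_hat, var_p_hat) {
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("`p_hat` must lie strictly in (0, 1); clamp boundary estimates ",
         "with clamp_proportion() first", call. = FALSE)
  }
  if (any(var_p_hat <= 0)) stop("`var_p_hat` must be positive", call. = FALSE)
  n_eff <- p_hat * (1 - p_hat) / var_p_hat
  tibble::tibble(y_eff = p_hat * n_eff, n_eff = n_eff)
}

#' @rdname effective_counts
#' @param n_raw Raw sample size used for the boundary clamp.
#' @export
clamp_proportion <- function(p_hat, n_raw) {
  stopifnot(all(n_raw > 0))
  pmin(pmax(p_hat, 1 / (2 * n_raw)), 1 - 1 / (2 * n_raw))
}

#' Aggregate true counts over classification dimensions
#'
#' Sums a per-cell count column over named dimensions, preserving the
#' remaining classification; the grand total is conserved. Used to align
#' latent true counts with data sources observed at a coarser
#' classification.
#'
#' @param counts Tibble with classification columns and a `y_true` column.
#' @param dims_to_sum Character vector of dimension columns to sum out
#'   (may be empty, giving the identity).
#' @return Tibble over the remaining dimensions with the summed `y_true`.
#' @export
aggregate_true_counts <- function(counts, dims_to_sum = character()) {
  counts <- tibble::as_tibble(counts)
  bad <- setdiff(dims_to_sum, names(counts))
  if (length(bad)) {
    stop("unknown dimension(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(dims_to_sum) == 0) return(counts)
  keep <- setdiff(names(counts), c(dims_to_sum, "y_true"))
  if (length(keep) == 0) {
    return(tibble::tibble(y_true = sum(counts$y_true)))
  }
  dplyr::summarise(dplyr::group_by(counts, dplyr::across(dplyr::all_of(keep))),
                   y_true = sum(.data$y_true), .groups = "drop")
}

#' Data-model log-likelihoods
#'
#' `survey_loglik()` evaluates the unbiased-normal survey data model: each
#' observed estimate contributes a normal log-density about the
#' correspondingly aggregated true count; unobserved cells contribute
#' nothing. `admin_loglik()` evaluates the log-scale administrative model
#' including the age-bias prior contribution (counted exactly once), and
#' `combined_loglik()` sums the data models of several datasets — the
#' likelihood of all sources is the product of the per-source likelihoods.
#'
#' @param y_true Tibble of true counts over the full grid (classification
#'   columns plus `y_true`).
#' @param dataset,datasets A `prev_dataset` / list of them.
#' @param gamma Named or positional numeric vector of age-bias terms (one
#'   per age label in the data).
#' @param sigma_y,sigma_gamma Admin noise sd (> 0) and bias-spread sd.
#' @param pi Optional tibble of prevalences (`pi` column) for
#'   `binomial_dataset` components.
#' @return A single log-likelihood value.
#' @export
survey_loglik <- function(y_true, dataset) {
  stopifnot(inherits(dataset, "prev_dataset"), dataset$kind == "survey")
  if (nrow(dataset$data) == 0) return(0)
  obs_dims <- intersect(names(y_true), names(dataset$data))
  obs_dims <- setdiff(obs_dims, c("value", "sd", "y_true"))
  joined <- dplyr::inner_join(dataset$data, y_true, by = obs_dims)
  if (nrow(joined) != nrow(dataset$data)) {
    stop("aggregated true counts do not cover all observed cells",
         call. = FALSE)
  }
  sum(stats::dnorm(joined$value, joined$y_true, joined$sd, log = TRUE))
}

#' @rdname survey_loglik
#' @export
admin_loglik <- function(y_true, dataset, gamma, sigma_y, sigma_gamma) {
  stopifnot(inherits(dataset, "prev_dataset"), dataset$kind == "admin",
            sigma_y > 0, sigma_gamma > 0)
  ages <- unique(as.character(dataset$data$age))
  if (is.null(names(gamma))) {
    stopifnot(length(gamma) == length(ages))
    names(gamma) <- ages
  }
  obs_dims <- setdiff(intersect(names(y_true), names(dataset$data)),
                      c("value", "y_true"))
  joined <- dplyr::inner_join(dataset$data, y_true, by = obs_dims)
  if (nrow(joined) != nrow(dataset$data)) {
    stop("true counts do not cover all observed admin cells", call. = FALSE)
  }
  if (any(joined$y_true <= 0)) {
    stop("true count is zero on an observed admin cell; latent counts ",
         "must stay positive where admin data exist", call. = FALSE)
  }
  sum(stats::dnorm(log(joined$value),
                   log(joined$y_true) + gamma[as.character(joined$age)],
                   sigma_y, log = TRUE)) +
    sum(stats::dnorm(gamma, 0, sigma_gamma, log = TRUE))
}

#' @rdname survey_loglik
#' @param params List of admin data-model parameters (`gamma`, `sigma_y`,
#'   `sigma_gamma`), required when `datasets` contains an admin source.
#' @export
combined_loglik <- function(y_true, datasets, params = list(), pi = NULL) {
  if (length(datasets) == 0) return(0)
  ll <- 0
  for (ds in datasets) {
    if (ds$kind == "survey") {
      agg <- aggregate_true_counts(y_true, intersect(ds$aggregate,
                                                     names(y_true)))
      ll <- ll + survey_loglik(agg, ds)
    } else if (ds$kind == "admin") {
      ll <- ll + admin_loglik(y_true, ds, params$gamma, params$sigma_y,
                              params$sigma_gamma)
    } else if (ds$kind == "binomial") {
      if (is.null(pi)) stop("binomial datasets need `pi`", call. = FALSE)
      obs_dims <- setdiff(intersect(names(pi), names(ds$data)),
                          c("y_eff", "n_eff", "pi"))
      joined <- dplyr::inner_join(ds$data, pi, by = obs_dims)
      ll <- ll + sum(lbinom_cont(joined$y_eff, joined$n_eff, joined$pi))
    } else {
      stop("unknown dataset kind `", ds$kind, "`", call. = FALSE)
    }
  }
  ll
}
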