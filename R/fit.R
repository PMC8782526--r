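#' MCMC configuration
#'
#' @param chains Number of chains (>= 1; >= 2 needed for convergence
#'   diagnostics).
#' @param warmup,iter Warmup (adaptation) and retained sampling iterations
#'   per chain.
#' @param thin Keep every `thin`-th sampling iteration.
#' @param seed Integer seed; recorded in the fit object.
#' @param rhat_threshold,ess_threshold Convergence flags: largest
#'   acceptable split-chain potential scale reduction and smallest
#'   acceptable effective sample size per monitored parameter.
#' @param moves_off Developer option: names of sampler moves to disable
#'   (any of `"swap"`, `"group_shift"`, `"joint"`); used in sampler
#'   validation, not in normal fits.
#' @return A list of class `prev_config`.
#' @export
prev_config <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1,
                        seed = 1, rhat_threshold = 1.05,
                        ess_threshold = 100, moves_off = character()) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold,
                 moves_off = moves_off),
            class = "prev_config")
}

#' Priors for the non-term parameters
#'
#' @param sigma Half-normal prior on the cell-level noise sd.
#' @param admin_sigma_y Prior on the administrative noise sd: either a
#'   [prior_half_normal()] (on the sd) or a [prior_scaled_inv_chisq()]
#'   (on the variance).
#' @param admin_sigma_gamma Half-normal prior on the age-bias spread.
#' @return A list of class `fit_priors`.
#' @export
fit_priors <- function(sigma = prior_half_normal(1),
                       admin_sigma_y = prior_half_normal(1),
                       admin_sigma_gamma = prior_half_normal(1)) {
  stopifnot(inherits(sigma, "prior_half_normal"),
            inherits(admin_sigma_y, "prior_half_normal") ||
              inherits(admin_sigma_y, "prior_scaled_inv_chisq"),
            inherits(admin_sigma_gamma, "prior_half_normal"))
  structure(list(sigma = sigma, admin_sigma_y = admin_sigma_y,
                 admin_sigma_gamma = admin_sigma_gamma),
            class = "fit_priors")
}

#' Fit the multi-source prevalence model
#'
#' Draws from the joint posterior of all unknowns — effect terms, trend
#' states and hyperparameters, cell-level noise, latent true counts,
#' administrative bias and noise parameters, and prevalences over the full
#' grid including forecast years. Forecast-year prevalences are drawn from
#' the same trend priors conditional on the sampled states, so estimation,
#' interpolation of data gaps, and forecasting are one operation. With an
#' empty dataset list the draws are prior-predictive.
#'
#' The sampler is a Gibbs/Metropolis hybrid: vectorised elementwise
#' random-walk Metropolis for cell logit-prevalences, a sequential
#' Metropolis sweep (compiled) for the continuous-relaxed latent counts
#' coupled through aggregated survey observations, conjugate Gibbs draws
#' for effect terms, forward-filter backward-sampling for damped-trend
#' states, slice sampling for scale hyperparameters and the damping
#' parameter, and a conjugate draw for the administrative variance when
#' its prior is scaled inverse-chi-squared. Proposal scales adapt during
#' warmup only.
#'
#' @param grid A [prev_grid()] or [panel_grid()].
#' @param terms A term structure from [default_terms()], [panel_terms()]
#'   or [term_structure()].
#' @param datasets List of [survey_dataset()], [binomial_dataset()],
#'   [admin_dataset()] objects (possibly empty for prior-predictive
#'   draws).
#' @param priors A [fit_priors()].
#' @param exposures Tibble of known populations at risk (classification
#'   columns plus `n_true`); required when any dataset uses the latent
#'   true-count layer (survey or admin kinds).
#' @param config A [prev_config()].
#' @return An object of class `prev_fit`.
#' @export
prev_fit <- function(grid, terms = default_terms(grid), datasets = list(),
                     priors = fit_priors(), exposures = NULL,
                     config = prev_config()) {
  stopifnot(inherits(grid, "prev_grid"), inherits(config, "prev_config"))
  t0 <- Sys.time()
  su <- fit_setup(grid, terms, datasets, priors, exposures)
  chains <- vector("list", config$chains)
  n_keep <- config$iter %/% config$thin
  for (ch in seq_len(config$chains)) {
    set.seed((config$seed + 7919L * ch) %% .Machine$integer.max)
    st <- init_state(su)
    total <- config$warmup + config$iter
    theta_draws <- matrix(NA_real_, n_keep, su$n_cells)
    hy <- collect_hypers(st, su)
    ef <- collect_effects(st, su)
    hyper_draws <- matrix(NA_real_, n_keep, length(hy),
                          dimnames = list(NULL, names(hy)))
    effect_draws <- matrix(NA_real_, n_keep, length(ef),
                           dimnames = list(NULL, names(ef)))
    kept <- 0L
    for (it in seq_len(total)) {
      adapt <- if (it <= config$warmup) min(0.25, 2 / sqrt(it)) else 0
      st <- update_theta_mh(st, su, adapt)
      st <- update_y(st, su, adapt,
                     joint = !"joint" %in% config$moves_off)
      if (!"group_shift" %in% config$moves_off) {
        st <- update_group_shift(st, su, adapt)
      }
      if (!"bias_swap" %in% config$moves_off) {
        st <- update_bias_swap(st, su, adapt)
      }
      st <- update_effects(st, su)
      st <- update_trends(st, su)
      st <- update_hier_tau(st, su)
      st <- update_sigma(st, su)
      if (!"ncp" %in% config$moves_off) {
        st <- update_sigma_ncp(st, su)
      }
      if (!"swap" %in% config$moves_off) {
        st <- update_variance_swap(st, su)
      }
      st <- draw_free_theta(st, su)
      st <- update_admin_params(st, su)
      if (it %% 100 == 0) { # guard against residual-update drift
        st$mu <- linear_predictor(st$effects, su$design)
      }
      if (it > config$warmup && (it - config$warmup) %% config$thin == 0) {
        kept <- kept + 1L
        theta_draws[kept, ] <- st$theta
        hyper_draws[kept, ] <- collect_hypers(st, su)
        effect_draws[kept, ] <- collect_effects(st, su)
      }
    }
    chains[[ch]] <- list(theta = theta_draws, hyper = hyper_draws,
                         effects = effect_draws)
  }
  fit <- structure(
    list(grid = grid, terms = terms, design = su$design, setup = su,
         datasets = datasets, priors = priors, config = config,
         chains = chains,
         runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "prev_fit"
  )
  fit$diagnostics <- if (config$chains >= 2) {
    convergence_report(fit)
  } else NULL
  if (!is.null(fit$diagnostics) && !attr(fit$diagnostics, "pass")) {
    warning("convergence diagnostics outside thresholds; inspect ",
            "convergence_report()", call. = FALSE)
  }
  fit
}

collect_hypers <- function(st, su) {
  out <- c(sigma = st$sigma)
  for (nm in names(st$trend)) {
    h <- st$trend[[nm]]$hypers
    v <- c(h$tau_beta, h$tau_alpha, h$tau_delta, h$phi)
    names(v) <- paste0(nm, c(".tau_beta", ".tau_alpha", ".tau_delta",
                             ".phi"))
    out <- c(out, v)
  }
  for (nm in names(st$hier_tau)) {
    out <- c(out, stats::setNames(st$hier_tau[[nm]], paste0(nm, ".tau")))
  }
  for (k in seq_along(su$admin)) {
    a <- su$admin[[k]]
    dsn <- names(su$admin)[k]
    g <- stats::setNames(st$gamma[[k]], paste0(dsn, ".gamma.", a$ages))
    out <- c(out, g,
             stats::setNames(st$sigma_y[[k]], paste0(dsn, ".sigma_y")),
             stats::setNames(st$sigma_gamma[[k]],
                             paste0(dsn, ".sigma_gamma")))
  }
  out
}

collect_effects <- function(st, su) {
  v <- unlist(st$effects, use.names = FALSE)
  names(v) <- unlist(purrr::imap(su$info, function(ti, nm) {
    paste0(nm, "[", ti$labels, "]")
  }), use.names = FALSE)
  v
}

#' @export
print.prev_fit <- function(x, ...) {
  cat("<prev_fit> ", x$grid$n_cells, " cells, ",
      length(x$datasets), " dataset(s), ",
      x$config$chains, " chain(s) x ", x$config$iter, " draws (warmup ",
      x$config$warmup, ")\n", sep = "")
  if (!is.null(x$diagnostics)) {
    cat("  max split-Rhat ", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
        ", min ESS ", round(min(x$diagnostics$ess, na.rm = TRUE)),
        if (attr(x$diagnostics, "pass")) " [converged]" else
          " [NOT converged]", "\n", sep = "")
  }
  cat("  runtime ", round(x$runtime, 1), "s, seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

# ---- draw accessors ------------------------------------------------------

#' Access posterior draws
#'
#' `prevalence_draws()` returns the pooled matrix of prevalence draws
#' (rows = draws, columns = grid cells in [grid_cells()] order);
#' `hyper_draws()` and `effect_draws()` return pooled tibbles of
#' hyperparameter and effect draws; `posterior_draw()` reassembles one
#' draw `k` into named effect vectors and data-model parameters (as needed
#' for replicate-data generation).
#'
#' @param fit A `prev_fit`.
#' @param k Pooled draw index.
#' @export
prevalence_draws <- function(fit) {
  stopifnot(inherits(fit, "prev_fit"))
  inv_logit(do.call(rbind, purrr::map(fit$chains, "theta")))
}

#' @rdname prevalence_draws
#' @export
hyper_draws <- function(fit) {
  tibble::as_tibble(do.call(rbind, purrr::map(fit$chains, "hyper")))
}

#' @rdname prevalence_draws
#' @export
effect_draws <- function(fit) {
  tibble::as_tibble(do.call(rbind, purrr::map(fit$chains, "effects")))
}

tidy_hyperparameters <- function(fit) {
  list(draws = hyper_draws(fit))
}

#' @rdname prevalence_draws
#' @export
posterior_draw <- function(fit, k) {
  hy <- do.call(rbind, purrr::map(fit$chains, "hyper"))
  ef <- do.call(rbind, purrr::map(fit$chains, "effects"))
  stopifnot(k >= 1, k <= nrow(hy))
  su <- fit$setup
  effects <- purrr::imap(su$info, function(ti, nm) {
    unname(ef[k, paste0(nm, "[", ti$labels, "]")])
  })
  out <- list(effects = effects, sigma = unname(hy[k, "sigma"]))
  for (dsn in names(su$admin)) {
    a <- su$admin[[dsn]]
    out$gamma[[dsn]] <- unname(hy[k, paste0(dsn, ".gamma.", a$ages)])
    out$sigma_y[[dsn]] <- unname(hy[k, paste0(dsn, ".sigma_y")])
  }
  out
}

# ---- summaries -----------------------------------------------------------

#' Interval summaries of draws
#'
#' Empirical median and central credible intervals computed by linear
#' interpolation of order statistics (quantile type 7). Intervals at
#' narrower levels are nested inside wider ones by construction.
#'
#' @param x Numeric vector of draws.
#' @param levels Central interval coverages.
#' @return A named numeric vector: `median`, then `lower_<pct>`,
#'   `upper_<pct>` per level.
#' @export
summary_intervals <- function(x, levels = c(0.5, 0.95)) {
  qs <- c(0.5, as.vector(rbind((1 - levels) / 2, 1 - (1 - levels) / 2)))
  v <- stats::quantile(x, qs, names = FALSE, type = 7)
  nm <- c("median", as.vector(rbind(paste0("lower_", 100 * levels),
                                    paste0("upper_", 100 * levels))))
  stats::setNames(v, nm)
}

#' Prevalence summary table
#'
#' Per-cell posterior medians and central credible intervals for
#' prevalence over the full grid, including interpolated and forecast
#' years.
#'
#' @param fit A `prev_fit`.
#' @param levels Central interval coverages (default 50% and 95%).
#' @return A tibble: one row per grid cell with the classification
#'   columns, `forecast`, `median`, and `lower_*`/`upper_*` columns.
#' @export
summarise_prevalence <- function(fit, levels = c(0.5, 0.95)) {
  pd <- prevalence_draws(fit)
  cells <- grid_cells(fit$grid)
  sm <- t(apply(pd, 2, summary_intervals, levels = levels))
  dplyr::bind_cols(cells, tibble::as_tibble(sm))
}

#' @rdname summarise_prevalence
#' @export
forecast_summaries <- function(fit, levels = c(0.5, 0.95)) {
  dplyr::filter(summarise_prevalence(fit, levels), .data$forecast)
}

#' National aggregate prevalence summaries
#'
#' Per draw, aggregates expected counts `n_true * pi` over all
#' non-time dimensions and divides by total exposure, then summarises by
#' year. Used for sensitivity-grid comparisons. Requires exposures (falls
#' back to unweighted means when the fit has none, e.g. binomial-path
#' fits).
#'
#' @inheritParams summarise_prevalence
#' @export
aggregate_prevalence <- function(fit, levels = c(0.5, 0.95)) {
  pd <- prevalence_draws(fit)
  cells <- grid_cells(fit$grid)
  w <- fit$setup$n_true
  if (is.null(w)) w <- rep(1, nrow(cells))
  w[is.na(w)] <- stats::median(w, na.rm = TRUE)
  years <- sort(unique(cells$year))
  out <- purrr::map_dfr(years, function(yy) {
    j <- cells$year == yy
    agg <- (pd[, j, drop = FALSE] %*% w[j]) / sum(w[j])
    v <- summary_intervals(agg, levels)
    dplyr::bind_cols(tibble::tibble(year = yy,
                                    forecast = yy > fit$grid$data_until),
                     tibble::as_tibble(t(v)))
  })
  out
}

# ---- convergence ---------------------------------------------------------

split_rhat <- function(x) {
  # x: iterations x chains; split each chain in half
  n <- nrow(x)
  h <- n %/% 2
  sp <- cbind(x[seq_len(h), , drop = FALSE],
              x[(n - h + 1):n, , drop = FALSE])
  mns <- colMeans(sp)
  vrs <- apply(sp, 2, stats::var)
  W <- mean(vrs)
  B <- h * stats::var(mns)
  if (W == 0) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

split_ess <- function(x, max_lag = 200) {
  n <- nrow(x)
  h <- n %/% 2
  sp <- cbind(x[seq_len(h), , drop = FALSE],
              x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(sp)
  vrs <- apply(sp, 2, stats::var)
  W <- mean(vrs)
  B <- h * stats::var(colMeans(sp))
  var_plus <- (h - 1) / h * W + B / h
  if (var_plus == 0) return(m * h)
  L <- min(max_lag, h - 2)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(sp[, j], lag.max = L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 1
  k <- 1
  prev_pair <- Inf
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    k <- k + 2
  }
  max(min(m * h, m * h / tau), 1)
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction (Rhat) and effective sample size
#' for every stored hyperparameter and effect, with an overall pass/fail
#' at the configured thresholds (attribute `pass`).
#'
#' @param fit A `prev_fit` with at least two chains.
#' @return A tibble with columns `parameter`, `rhat`, `ess`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "prev_fit"))
  if (fit$config$chains < 2) {
    stop("convergence diagnostics need at least 2 chains", call. = FALSE)
  }
  mats <- purrr::map(fit$chains, ~ cbind(.x$hyper, .x$effects))
  pn <- colnames(mats[[1]])
  res <- purrr::map_dfr(seq_along(pn), function(j) {
    x <- sapply(mats, function(mm) mm[, j])
    if (stats::sd(x) < 1e-12) {
      return(tibble::tibble(parameter = pn[j], rhat = NA_real_,
                            ess = NA_real_))
    }
    tibble::tibble(parameter = pn[j], rhat = split_rhat(x),
                   ess = split_ess(x))
  })
  pass <- all(res$rhat < fit$config$rhat_threshold, na.rm = TRUE) &&
    all(res$ess > fit$config$ess_threshold, na.rm = TRUE)
  attr(res, "pass") <- pass
  res
}
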