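#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy method for fitted prevalence models
#'
#' One row per monitored scalar parameter (hyperparameters and effects)
#' with posterior median, central intervals, and convergence diagnostics.
#'
#' @param x A `prev_fit`.
#' @param levels Central interval coverages.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `median`,
#'   `lower_*`/`upper_*`, `rhat`, `ess`.
#' @export
tidy.prev_fit <- function(x, levels = c(0.5, 0.95), ...) {
  draws <- dplyr::bind_cols(hyper_draws(x), effect_draws(x))
  sm <- t(vapply(draws, summary_intervals, numeric(1 + 2 * length(levels)),
                 levels = levels))
  out <- dplyr::bind_cols(tibble::tibble(parameter = colnames(draws)),
                          tibble::as_tibble(sm))
  if (!is.null(x$diagnostics)) {
    out <- dplyr::left_join(out, x$diagnostics, by = "parameter")
  }
  out
}

#' Glance method for fitted prevalence models
#'
#' @param x A `prev_fit`.
#' @param ... Unused.
#' @return A one-row tibble: draw counts, worst diagnostics, convergence
#'   flag, runtime, seed.
#' @export
glance.prev_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    chains = x$config$chains,
    iter = x$config$iter,
    warmup = x$config$warmup,
    n_draws = x$config$chains * (x$config$iter %/% x$config$thin),
    max_rhat = if (!is.null(d)) max(d$rhat, na.rm = TRUE) else NA_real_,
    min_ess = if (!is.null(d)) min(d$ess, na.rm = TRUE) else NA_real_,
    converged = if (!is.null(d)) attr(d, "pass") else NA,
    runtime_s = x$runtime,
    seed = x$config$seed
  )
}

#' Plot prevalence estimates and forecasts
#'
#' Ribbon plot of posterior medians with 50% and 95% credible bands by
#' year, faceted by age and sex. For subnational grids supply a summary
#' table filtered to the series of interest, or use
#' [aggregate_prevalence()] for the national aggregate.
#'
#' @param summaries Output of [summarise_prevalence()] or
#'   [aggregate_prevalence()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(summaries) {
  p <- ggplot2::ggplot(summaries, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower_95,
                                      ymax = .data$upper_95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower_50,
                                      ymax = .data$upper_50),
                         fill = "steelblue", alpha = 0.45) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "white") +
    ggplot2::labs(y = "prevalence", x = NULL) +
    ggplot2::theme_minimal()
  if (all(c("age", "sex") %in% names(summaries))) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$sex), cols = ggplot2::vars(.data$age))
  }
  p
}

#' @rdname plot_prevalence
#' @param object A `prev_fit`.
#' @param ... Passed to [summarise_prevalence()].
#' @export
autoplot.prev_fit <- function(object, ...) {
  sm <- summarise_prevalence(object, ...)
  # collapse singleton region/urban columns for national grids
  for (nm in c("region", "urban")) {
    if (nm %in% names(sm) && length(unique(sm[[nm]])) == 1) {
      sm[[nm]] <- NULL
    }
  }
  plot_prevalence(sm)
}
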