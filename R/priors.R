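#' Prior family constructors
#'
#' Small tagged objects describing the prior families used throughout the
#' model: normal priors for effect terms (sd 1 for age/sex-type effects,
#' sd 10 for the intercept), half-normal priors for scale parameters,
#' a Beta prior rescaled to an interval for the damping parameter phi,
#' a scaled inverse-chi-squared prior for the administrative error variance,
#' exchangeable hierarchical normal priors for region/urban/country-type
#' effects, and the damped-linear-trend family for time terms.
#'
#' @param mean,sd Normal location and scale (`sd > 0`).
#' @param a,b Beta shape parameters (`> 0`).
#' @param lo,hi Support of the rescaled Beta (`lo < hi`).
#' @param df,scale2 Degrees of freedom and scale-squared of the scaled
#'   inverse-chi-squared distribution (`> 0`).
#' @param tau_prior Prior (a `prior_half_normal()`) on the hierarchical sd.
#' @param tau_beta,tau_alpha,tau_delta Priors on the damped-trend
#'   innovation sds (each a `prior_half_normal()`).
#' @param phi Prior on the damping parameter (a `prior_scaled_beta()`).
#' @param init_sd Prior sd of the initial level and drift states.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), sd > 0)
  structure(list(mean = mean, sd = sd), class = c("prior_normal", "prev_prior"))
}

#' @rdname priors
#' @export
prior_half_normal <- function(sd = 1) {
  stopifnot(sd > 0)
  structure(list(sd = sd), class = c("prior_half_normal", "prev_prior"))
}

#' @rdname priors
#' @export
prior_scaled_beta <- function(a = 2, b = 2, lo = 0.8, hi = 1) {
  stopifnot(a > 0, b > 0, lo >= 0, lo < hi, hi <= 1)
  structure(list(a = a, b = b, lo = lo, hi = hi),
            class = c("prior_scaled_beta", "prev_prior"))
}

#' @rdname priors
#' @export
prior_scaled_inv_chisq <- function(df, scale2) {
  stopifnot(df > 0, scale2 > 0)
  structure(list(df = df, scale2 = scale2),
            class = c("prior_scaled_inv_chisq", "prev_prior"))
}

#' @rdname priors
#' @export
prior_hier_normal <- function(tau_prior = prior_half_normal(1)) {
  stopifnot(inherits(tau_prior, "prior_half_normal"))
  structure(list(tau_prior = tau_prior),
            class = c("prior_hier_normal", "prev_prior"))
}

#' @rdname priors
#' @export
prior_damped_trend <- function(tau_beta = prior_half_normal(1),
                               tau_alpha = prior_half_normal(1),
                               tau_delta = prior_half_normal(1),
                               phi = prior_scaled_beta(2, 2, 0.8, 1),
                               init_sd = 1) {
  stopifnot(
    inherits(tau_beta, "prior_half_normal"),
    inherits(tau_alpha, "prior_half_normal"),
    inherits(tau_delta, "prior_half_normal"),
    inherits(phi, "prior_scaled_beta"),
    init_sd > 0
  )
  structure(
    list(tau_beta = tau_beta, tau_alpha = tau_alpha, tau_delta = tau_delta,
         phi = phi, init_sd = init_sd),
    class = c("prior_damped_trend", "prev_prior")
  )
}

#' @export
print.prev_prior <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  flat <- x[!vapply(x, inherits, logical(1), "prev_prior")]
  if (length(flat)) {
    cat(paste(names(flat), unlist(flat), sep = "=", collapse = ", "))
  }
  cat("\n")
  nested <- x[vapply(x, inherits, logical(1), "prev_prior")]
  for (nm in names(nested)) {
    cat("  ", nm, ": ", sep = "")
    print(nested[[nm]])
  }
  invisible(x)
}

# ---- log densities -------------------------------------------------------

ldens_half_normal <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

ldens_scaled_beta <- function(x, p) {
  u <- (x - p$lo) / (p$hi - p$lo)
  ifelse(u <= 0 | u >= 1, -Inf,
         stats::dbeta(u, p$a, p$b, log = TRUE) - log(p$hi - p$lo))
}

# density of the scaled inverse-chi-squared on the variance scale
ldens_scaled_inv_chisq <- function(x, df, scale2) {
  half <- df / 2
  ifelse(x <= 0, -Inf,
         half * log(half) + half * log(scale2) - lgamma(half) -
           (half + 1) * log(x) - half * scale2 / x)
}

#' Scaled inverse-chi-squared quantiles and intervals
#'
#' The scaled inverse-chi-squared distribution with degrees of freedom `df`
#' and scale-squared `scale2` is the law of `df * scale2 / X` with
#' `X ~ chi-squared(df)`. It is used as a prior for the administrative
#' data-model error variance: unlike a half-normal, its mode is away from
#' zero, so it does not favour treating administrative noise as real signal.
#'
#' @param prior A [prior_scaled_inv_chisq()].
#' @param q Probability (or vector of probabilities) in (0, 1).
#' @param level Central interval coverage in (0, 1).
#' @return `scaled_inv_chisq_quantile()` returns the quantile(s);
#'   `central_interval()` a named vector `c(lo, hi)`.
#' @examples
#' central_interval(prior_scaled_inv_chisq(30, 0.015), 0.95)
#' @export
scaled_inv_chisq_quantile <- function(prior, q) {
  stopifnot(inherits(prior, "prior_scaled_inv_chisq"))
  if (any(q <= 0 | q >= 1)) stop("`q` must lie in (0, 1)", call. = FALSE)
  prior$df * prior$scale2 / stats::qchisq(1 - q, prior$df)
}

#' @rdname scaled_inv_chisq_quantile
#' @export
central_interval <- function(prior, level = 0.95) {
  stopifnot(level > 0, level < 1)
  lo <- scaled_inv_chisq_quantile(prior, (1 - level) / 2)
  hi <- scaled_inv_chisq_quantile(prior, 1 - (1 - level) / 2)
  c(lo = lo, hi = hi)
}

# draw from a prior family (used by the synthetic-data generator and
# prior-predictive checks)
draw_prior <- function(prior, n = 1) {
  switch(class(prior)[1],
    prior_normal = stats::rnorm(n, prior$mean, prior$sd),
    prior_half_normal = abs(stats::rnorm(n, 0, prior$sd)),
    prior_scaled_beta = prior$lo +
      (prior$hi - prior$lo) * stats::rbeta(n, prior$a, prior$b),
    prior_scaled_inv_chisq = prior$df * prior$scale2 /
      stats::rchisq(n, prior$df),
    stop("cannot draw directly from a ", class(prior)[1], call. = FALSE)
  )
}
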