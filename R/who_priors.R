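#' Effective counts from a point estimate and 95% interval
#'
#' International panel estimates come as prevalence point estimates with
#' 95% intervals. Inverting a normal approximation, the implied standard
#' error is `(hi - lo) / (2 * 1.96)` and the effective counts are
#' `n_eff = p (1 - p) / SE^2`, `y_eff = p * n_eff`. Asymmetric intervals
#' use the same total-width rule and are flagged with a message.
#'
#' @param p Point estimate(s) in (0, 1).
#' @param lo,hi Interval endpoints with `lo < p < hi`.
#' @return A tibble with columns `y_eff`, `n_eff`.
#' @examples
#' panel_counts_from_interval(0.2, 0.2 - 1.96 * 0.04, 0.2 + 1.96 * 0.04)
#' @export
panel_counts_from_interval <- function(p, lo, hi) {
  if (any(hi <= lo)) stop("degenerate interval: need lo < hi", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (any(p <= lo | p >= hi)) {
    stop("point estimate must lie inside its interval", call. = FALSE)
  }
  asym <- abs((hi - p) - (p - lo)) > 1e-8 * (hi - lo)
  if (any(asym)) {
    message(sum(asym), " asymmetric interval(s); using total width")
  }
  se <- (hi - lo) / (2 * stats::qnorm(0.975))
  n_eff <- p * (1 - p) / se^2
  tibble::tibble(y_eff = p * n_eff, n_eff = n_eff)
}

#' Closed-form approximation of extracted posterior samples
#'
#' After fitting the panel model, the posterior samples of each trend
#' innovation sd are approximated by a half-normal distribution by moment
#' matching: for HalfNormal(s), E\[x^2\] = s^2, so `s = sqrt(mean(x^2))`.
#' The damping parameter phi is mapped to `u = (phi - lo)/(hi - lo)` and a
#' Beta(a, b) is fitted to u by matching mean and variance.
#'
#' @param samples Numeric vector of posterior samples (nonnegative for
#'   `approximate_half_normal()`; inside `range` for
#'   `approximate_phi_prior()`).
#' @param range Support of phi, default `c(0.8, 1)`.
#' @return `approximate_half_normal()`: a [prior_half_normal()];
#'   `approximate_phi_prior()`: a [prior_scaled_beta()].
#' @export
approximate_half_normal <- function(samples) {
  if (length(samples) < 3) stop("too few samples", call. = FALSE)
  if (any(samples < 0)) stop("samples must be nonnegative", call. = FALSE)
  sd <- sqrt(mean(samples^2))
  if (sd == 0) {
    warning("all samples are zero: degenerate half-normal approximation")
    return(structure(list(sd = 0), class = c("prior_half_normal",
                                             "prev_prior")))
  }
  prior_half_normal(sd)
}

#' @rdname approximate_half_normal
#' @export
approximate_phi_prior <- function(samples, range = c(0.8, 1)) {
  if (any(samples < range[1] | samples > range[2])) {
    stop("samples outside [", range[1], ", ", range[2], "]", call. = FALSE)
  }
  u <- (samples - range[1]) / (range[2] - range[1])
  m <- mean(u)
  v <- stats::var(u)
  if (!is.finite(v) || v <= 0) stop("zero-variance samples", call. = FALSE)
  s <- m * (1 - m) / v - 1
  if (s <= 0) {
    stop("sample variance exceeds the Beta maximum for its mean",
         call. = FALSE)
  }
  prior_scaled_beta(a = m * s, b = (1 - m) * s, lo = range[1], hi = range[2])
}

#' Extracted trend hyperpriors
#'
#' Bundles the closed-form hyperpriors for the four damped-trend
#' parameters, with the variance-inflation factor applied so far.
#' `inflate_prior()` multiplies every variance by `factor`: half-normal
#' sds are scaled by `sqrt(factor)`, and the Beta on the rescaled phi has
#' its variance multiplied by `factor` holding the mean fixed (clamped,
#' with a warning, at the mean-constrained maximum). Inflation composes
#' multiplicatively: factor 2 applied twice equals factor 4.
#'
#' @param tau_beta,tau_alpha,tau_delta [prior_half_normal()] objects.
#' @param phi A [prior_scaled_beta()].
#' @param inflation Variance-inflation factor already applied.
#' @return A `trend_hyperpriors` object.
#' @export
trend_hyperpriors <- function(tau_beta, tau_alpha, tau_delta, phi,
                              inflation = 1) {
  stopifnot(inherits(tau_beta, "prior_half_normal"),
            inherits(tau_alpha, "prior_half_normal"),
            inherits(tau_delta, "prior_half_normal"),
            inherits(phi, "prior_scaled_beta"), inflation >= 1)
  structure(list(tau_beta = tau_beta, tau_alpha = tau_alpha,
                 tau_delta = tau_delta, phi = phi, inflation = inflation),
            class = "trend_hyperpriors")
}

#' @rdname trend_hyperpriors
#' @param h A `trend_hyperpriors` object.
#' @param factor Variance-inflation factor (>= 1; the reported sensitivity
#'   variants use 1, 2, and 4).
#' @export
inflate_prior <- function(h, factor) {
  stopifnot(inherits(h, "trend_hyperpriors"), factor >= 1)
  if (factor == 1) return(h)
  infl_hn <- function(p) prior_half_normal(p$sd * sqrt(factor))
  infl_beta <- function(p) {
    m <- p$a / (p$a + p$b)
    v <- m * (1 - m) / (p$a + p$b + 1)
    v_new <- v * factor
    v_max <- m * (1 - m)
    if (v_new >= v_max) {
      warning("requested Beta variance exceeds the mean-constrained ",
              "maximum; clamping")
      v_new <- v_max * 0.999
    }
    s <- m * (1 - m) / v_new - 1
    prior_scaled_beta(a = m * s, b = (1 - m) * s, lo = p$lo, hi = p$hi)
  }
  trend_hyperpriors(
    tau_beta = infl_hn(h$tau_beta),
    tau_alpha = infl_hn(h$tau_alpha),
    tau_delta = infl_hn(h$tau_delta),
    phi = infl_beta(h$phi),
    inflation = h$inflation * factor
  )
}

#' @rdname trend_hyperpriors
#' @param init_sd Initial-state prior sd passed through to the trend prior.
#' @export
hyperpriors_to_trend_prior <- function(h, init_sd = 1) {
  stopifnot(inherits(h, "trend_hyperpriors"))
  prior_damped_trend(tau_beta = h$tau_beta, tau_alpha = h$tau_alpha,
                     tau_delta = h$tau_delta, phi = h$phi,
                     init_sd = init_sd)
}

#' Fit the international panel model and extract trend hyperpriors
#'
#' Fits the country-by-sex-by-year panel model — a binomial likelihood on
#' effective counts with a logit-linear predictor containing an intercept,
#' exchangeable country and country-sex effects, a sex effect, and a
#' damped-linear-trend year effect — then discards everything except the
#' posterior samples of the year-trend hyperparameters (tau_beta,
#' tau_alpha, tau_delta, phi) and approximates those by closed-form
#' hyperpriors. `inflate` multiplies the approximated variances (default 2,
#' reflecting that smoothed panel series understate year-to-year
#' variation).
#'
#' @param panel Tibble with columns `country`, `sex`, `year`, and either
#'   (`estimate`, `lower`, `upper`) or (`y_eff`, `n_eff`).
#' @param config A [prev_config()].
#' @param inflate Variance-inflation factor applied to the extracted
#'   hyperpriors.
#' @return A list: `hyperpriors` (a `trend_hyperpriors`), `samples`
#'   (tibble of the four hyperparameter draws), `fit` (the panel
#'   `prev_fit` object).
#' @export
extract_panel_hyperpriors <- function(panel, config = prev_config(),
                                      inflate = 2) {
  fit <- fit_panel_model(panel, config = config)
  s <- fit$samples
  h <- trend_hyperpriors(
    tau_beta = approximate_half_normal(s$tau_beta),
    tau_alpha = approximate_half_normal(s$tau_alpha),
    tau_delta = approximate_half_normal(s$tau_delta),
    phi = approximate_phi_prior(s$phi)
  )
  list(hyperpriors = inflate_prior(h, inflate), samples = s, fit = fit$fit)
}

#' @rdname extract_panel_hyperpriors
#' @export
fit_panel_model <- function(panel, config = prev_config()) {
  panel <- tibble::as_tibble(panel)
  need <- c("country", "sex", "year")
  if (!all(need %in% names(panel))) {
    stop("panel needs columns country, sex, year", call. = FALSE)
  }
  if (!all(c("y_eff", "n_eff") %in% names(panel))) {
    ec <- panel_counts_from_interval(panel$estimate, panel$lower,
                                     panel$upper)
    panel$y_eff <- ec$y_eff
    panel$n_eff <- ec$n_eff
  }
  if (length(unique(panel$country)) < 2) {
    stop("panel must contain at least two countries (hierarchical country ",
         "sd is unidentifiable from one)", call. = FALSE)
  }
  if (length(unique(panel$year)) < 3) {
    stop("panel must span at least three years", call. = FALSE)
  }
  grid <- panel_grid(countries = sort(unique(panel$country)),
                     sexes = sort(unique(as.character(panel$sex))),
                     years = seq(min(panel$year), max(panel$year)))
  terms <- panel_terms(grid)
  ds <- binomial_dataset(panel[, c("country", "sex", "year", "y_eff",
                                   "n_eff")], name = "panel")
  fit <- prev_fit(grid, terms, datasets = list(ds), config = config)
  hyp <- tidy_hyperparameters(fit)
  samples <- tibble::tibble(
    tau_beta = hyp$draws[["year.tau_beta"]],
    tau_alpha = hyp$draws[["year.tau_alpha"]],
    tau_delta = hyp$draws[["year.tau_delta"]],
    phi = hyp$draws[["year.phi"]]
  )
  list(samples = samples, fit = fit)
}
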