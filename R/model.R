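#' Logistic transforms and the continuous binomial log-density
#'
#' `lbinom_cont()` is the continuous extension of the binomial log-pmf via
#' log-gamma functions, valid for non-integer counts such as the effective
#' counts produced from design-based survey estimates; it coincides with
#' `dbinom(..., log = TRUE)` at integer arguments.
#'
#' @param y Counts (possibly non-integer), `0 <= y <= n`.
#' @param n Sample sizes (> 0).
#' @param p Probabilities in (0, 1) (endpoints allowed where the limit is
#'   finite).
#' @return Numeric vector of log-densities.
#' @keywords internal
#' @export
lbinom_cont <- function(y, n, p) {
  if (any(y < 0 | y > n)) stop("`y` must lie in [0, n]", call. = FALSE)
  t1 <- ifelse(y > 0, y * log(p), 0)
  t2 <- ifelse(n - y > 0, (n - y) * log1p(-p), 0)
  lgamma(n + 1) - lgamma(y + 1) - lgamma(n - y + 1) + t1 + t2
}

inv_logit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p) - log1p(-p)

#' System-model count likelihood
#'
#' Log-likelihood of latent true case counts given prevalences: the sum of
#' (continuously extended) binomial log-densities
#' `y_true ~ Binomial(pi, n_true)` over cells.
#'
#' @param y_true,n_true Count and exposure vectors/arrays of equal shape,
#'   `0 <= y_true <= n_true`.
#' @param pi Prevalence values in \code{[0, 1]}, same shape.
#' @return A single log-likelihood value.
#' @export
system_loglik <- function(y_true, n_true, pi) {
  stopifnot(length(y_true) == length(n_true), length(pi) == length(y_true))
  if (any(pi < 0 | pi > 1)) stop("`pi` must lie in [0, 1]", call. = FALSE)
  sum(lbinom_cont(y_true, n_true, pi))
}

#' System states
#'
#' Bundles one full configuration of the system model: effect vectors per
#' term, the cell-level noise sd `sigma`, logit-prevalences `theta` over
#' all grid cells, trend states (level `alpha` and drift `delta` chains,
#' including the time-0 state in column 1) with their hyperparameters for
#' each time-bearing term, and hierarchical sds for exchangeable terms.
#'
#' @param effects Named list of effect vectors (one per design term).
#' @param sigma Cell-level noise sd (>= 0).
#' @param theta Logit-prevalence vector over grid cells.
#' @param trend Named list (one entry per time-bearing term): each a list
#'   with `alpha`, `delta` (matrices `n_chain x (n_time + 1)`) and `hypers`
#'   (a [trend_hypers()]).
#' @param hier_tau Named list of sds for `prior_hier_normal` terms.
#' @return A list of class `system_state`.
#' @export
system_state <- function(effects, sigma, theta, trend = list(),
                         hier_tau = list()) {
  stopifnot(sigma >= 0)
  structure(list(effects = effects, sigma = sigma, theta = theta,
                 trend = trend, hier_tau = hier_tau),
            class = "system_state")
}

#' Joint log-prior density of a system state
#'
#' Sums the log-densities of every effect under its prior family, the
#' trend-state dynamics and their hyperpriors, the hierarchical sds, the
#' cell-level logit-normal term, and the half-normal prior on `sigma`.
#' Returns `-Inf` (not an error) for boundary states such as prevalences
#' at 0 or 1 or phi at the edge of its range.
#'
#' @param state A [system_state()].
#' @param design A `prev_design` from [build_design()].
#' @param sigma_prior Prior on `sigma` (default half-normal sd 1).
#' @return A single log-density value (possibly `-Inf`).
#' @export
log_prior <- function(state, design, sigma_prior = prior_half_normal(1)) {
  stopifnot(inherits(state, "system_state"), inherits(design, "prev_design"))
  lp <- 0
  for (nm in names(design)) {
    d <- design[[nm]]
    b <- state$effects[[nm]]
    if (is.null(b) || length(b) != d$n_levels) {
      stop("state is missing or mis-shaped for term `", nm, "`",
           call. = FALSE)
    }
    p <- d$prior
    if (inherits(p, "prior_normal")) {
      lp <- lp + sum(stats::dnorm(b, p$mean, p$sd, log = TRUE))
    } else if (inherits(p, "prior_hier_normal")) {
      tau <- state$hier_tau[[nm]]
      if (is.null(tau)) stop("missing hierarchical sd for `", nm, "`",
                             call. = FALSE)
      lp <- lp + sum(stats::dnorm(b, 0, tau, log = TRUE)) +
        ldens_half_normal(tau, p$tau_prior$sd)
    } else if (inherits(p, "prior_damped_trend")) {
      lp <- lp + trend_log_prior(b, d, state$trend[[nm]], p)
    } else {
      stop("unsupported prior family for term `", nm, "`", call. = FALSE)
    }
  }
  mu <- linear_predictor(state$effects, design)
  lp <- lp + sum(stats::dnorm(state$theta, mu, state$sigma, log = TRUE)) +
    ldens_half_normal(state$sigma, sigma_prior$sd)
  if (is.nan(lp)) -Inf else lp
}

# log-density of trend states + beta levels + hyperpriors for one
# time-bearing term; beta vector is laid out chain-fastest
trend_log_prior <- function(beta, d, tr, prior) {
  if (is.null(tr)) stop("missing trend state for a time-bearing term",
                        call. = FALSE)
  h <- tr$hypers
  Tn <- d$n_time
  nc <- d$n_chain
  bmat <- matrix(beta, nc, Tn)
  al <- tr$alpha # nc x (Tn + 1), column 1 = time 0
  de <- tr$delta
  lp <- sum(stats::dnorm(bmat, al[, -1, drop = FALSE], h$tau_beta, log = TRUE))
  lp <- lp + sum(stats::dnorm(al[, -1, drop = FALSE],
                              al[, -(Tn + 1), drop = FALSE] +
                                de[, -(Tn + 1), drop = FALSE],
                              h$tau_alpha, log = TRUE))
  lp <- lp + sum(stats::dnorm(de[, -1, drop = FALSE],
                              h$phi * de[, -(Tn + 1), drop = FALSE],
                              h$tau_delta, log = TRUE))
  lp <- lp + sum(stats::dnorm(al[, 1], 0, prior$init_sd, log = TRUE)) +
    sum(stats::dnorm(de[, 1], 0, prior$init_sd, log = TRUE))
  lp + ldens_half_normal(h$tau_beta, prior$tau_beta$sd) +
    ldens_half_normal(h$tau_alpha, prior$tau_alpha$sd) +
    ldens_half_normal(h$tau_delta, prior$tau_delta$sd) +
    ldens_scaled_beta(h$phi, prior$phi)
}
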