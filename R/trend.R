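#' Simulate a damped linear trend
#'
#' The damped-linear-trend prior is a local-linear state-space model: the
#' time effect equals a level plus noise, the level advances by the
#' previous drift, and the drift is shrunk towards zero by a damping
#' factor phi each year,
#' \deqn{\beta_t = \alpha_t + \epsilon^\beta_t,\quad
#'       \alpha_t = \alpha_{t-1} + \delta_{t-1} + \epsilon^\alpha_t,\quad
#'       \delta_t = \phi\,\delta_{t-1} + \epsilon^\delta_t,}
#' with innovation sds `tau_beta`, `tau_alpha`, `tau_delta`. With phi = 1
#' it is a random walk with drift; phi < 1 tempers long-run extrapolation.
#'
#' @param hypers A [trend_hypers()] object.
#' @param init_level,init_drift State at time 0 (the transition is applied
#'   before the first returned value).
#' @param n_time Number of time steps to simulate (>= 1).
#' @return A tibble with columns `time` (1..n_time), `alpha`, `delta`,
#'   `beta`.
#' @examples
#' simulate_damped_trend(trend_hypers(0, 0, 0, 1), 1, 0.5, 4)$beta # 1.5 2 2.5 3
#' @export
simulate_damped_trend <- function(hypers, init_level = 0, init_drift = 0,
                                  n_time) {
  stopifnot(inherits(hypers, "trend_hypers"))
  if (n_time < 1) stop("`n_time` must be >= 1", call. = FALSE)
  n_time <- as.integer(n_time)
  alpha <- delta <- beta <- numeric(n_time)
  a <- init_level
  d <- init_drift
  for (t in seq_len(n_time)) {
    a_new <- a + d + stats::rnorm(1, 0, hypers$tau_alpha)
    d_new <- hypers$phi * d + stats::rnorm(1, 0, hypers$tau_delta)
    a <- a_new
    d <- d_new
    alpha[t] <- a
    delta[t] <- d
    beta[t] <- a + stats::rnorm(1, 0, hypers$tau_beta)
  }
  tibble::tibble(time = seq_len(n_time), alpha = alpha, delta = delta,
                 beta = beta)
}

#' @rdname simulate_damped_trend
#' @param tau_beta,tau_alpha,tau_delta Nonnegative innovation sds.
#' @param phi Damping factor, restricted to `phi_range`.
#' @param phi_range Allowed range for phi (default `[0.8, 1]`).
#' @export
trend_hypers <- function(tau_beta, tau_alpha, tau_delta, phi,
                         phi_range = c(0.8, 1)) {
  stopifnot(tau_beta >= 0, tau_alpha >= 0, tau_delta >= 0)
  if (phi < phi_range[1] || phi > phi_range[2]) {
    stop("`phi` must lie in [", phi_range[1], ", ", phi_range[2], "]",
         call. = FALSE)
  }
  structure(list(tau_beta = tau_beta, tau_alpha = tau_alpha,
                 tau_delta = tau_delta, phi = phi, phi_range = phi_range),
            class = "trend_hypers")
}

# ---- forward-filter backward-sample --------------------------------------
# Joint draw of the level/drift states (alpha_t, delta_t), t = 0..T, from
# a linear-Gaussian model with level observations obs_t ~ N(alpha_t, R_t)
# at t = 1..T (R_t = Inf or obs_t = NA means no observation at t), trend
# transition with damping phi and innovation variances tau_alpha^2,
# tau_delta^2, and N(0, init_sd^2) priors on the time-0 state. All 2x2
# algebra is explicit scalar arithmetic for speed; covariances are kept
# symmetric by construction and variances floored against degeneracy.
ffbs_trend <- function(obs, obs_var, hypers, init_sd = 1) {
  T <- length(obs)
  eps <- 1e-12
  phi <- hypers$phi
  qa <- max(hypers$tau_alpha^2, eps)
  qd <- max(hypers$tau_delta^2, eps)
  m1 <- m2 <- numeric(T + 1)
  p11 <- p12 <- p22 <- numeric(T + 1)
  m1p <- m2p <- q11 <- q12 <- q22 <- numeric(T)
  p11[1] <- init_sd^2
  p22[1] <- init_sd^2
  for (t in seq_len(T)) {
    # predict
    a1 <- m1[t] + m2[t]
    a2 <- phi * m2[t]
    r11 <- p11[t] + 2 * p12[t] + p22[t] + qa
    r12 <- phi * (p12[t] + p22[t])
    r22 <- phi^2 * p22[t] + qd
    m1p[t] <- a1; m2p[t] <- a2
    q11[t] <- r11; q12[t] <- r12; q22[t] <- r22
    # update
    if (is.finite(obs_var[t]) && !is.na(obs[t])) {
      S <- r11 + obs_var[t]
      k1 <- r11 / S
      k2 <- r12 / S
      e <- obs[t] - a1
      m1[t + 1] <- a1 + k1 * e
      m2[t + 1] <- a2 + k2 * e
      p11[t + 1] <- r11 - k1 * r11
      p12[t + 1] <- r12 - k1 * r12
      p22[t + 1] <- r22 - k2 * r12
    } else {
      m1[t + 1] <- a1; m2[t + 1] <- a2
      p11[t + 1] <- r11; p12[t + 1] <- r12; p22[t + 1] <- r22
    }
  }
  al <- de <- numeric(T + 1)
  zs <- stats::rnorm(2 * (T + 1))
  x <- rnorm2(m1[T + 1], m2[T + 1], p11[T + 1], p12[T + 1], p22[T + 1],
              zs[2 * T + 1], zs[2 * T + 2])
  al[T + 1] <- x[1]; de[T + 1] <- x[2]
  for (t in rev(seq_len(T))) {
    # smooth: x_{t-1} | x_t; A = P_t F^T, G = A %*% solve(P_pred),
    # with F = [[1,1],[0,phi]]
    A11 <- p11[t] + p12[t]
    A12 <- phi * p12[t]
    A21 <- p12[t] + p22[t]
    A22 <- phi * p22[t]
    det <- q11[t] * q22[t] - q12[t]^2
    if (det <= eps^2) det <- eps^2
    i11 <- q22[t] / det; i12 <- -q12[t] / det; i22 <- q11[t] / det
    G11 <- A11 * i11 + A12 * i12
    G12 <- A11 * i12 + A12 * i22
    G21 <- A21 * i11 + A22 * i12
    G22 <- A21 * i12 + A22 * i22
    e1 <- al[t + 1] - m1p[t]
    e2 <- de[t + 1] - m2p[t]
    mu1 <- m1[t] + G11 * e1 + G12 * e2
    mu2 <- m2[t] + G21 * e1 + G22 * e2
    v11 <- p11[t] - (G11 * A11 + G12 * A12)
    v12 <- p12[t] - (G11 * A21 + G12 * A22)
    v22 <- p22[t] - (G21 * A21 + G22 * A22)
    x <- rnorm2(mu1, mu2, v11, v12, v22, zs[2 * t - 1], zs[2 * t])
    al[t] <- x[1]; de[t] <- x[2]
  }
  list(alpha = al, delta = de) # index 1 = time 0
}

# bivariate normal draw via explicit Cholesky, guarding degeneracy
rnorm2 <- function(mu1, mu2, v11, v12, v22, z1, z2) {
  v11 <- max(v11, 0)
  l11 <- sqrt(v11)
  l21 <- if (l11 > 0) v12 / l11 else 0
  l22 <- sqrt(max(v22 - l21^2, 0))
  c(mu1 + l11 * z1, mu2 + l21 * z1 + l22 * z2)
}
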