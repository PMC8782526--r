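# Internal sampling machinery: slice sampler, constrained normal draws,
# and the per-iteration Gibbs/Metropolis updates used by prev_fit().

# univariate slice sampler (Neal 2003): stepping out + shrinkage, with
# optional hard bounds. logf must be finite at x0.
slice1 <- function(x0, logf, w = 0.5, lo = -Inf, hi = Inf, max_steps = 30) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  z <- f0 - stats::rexp(1)
  if (is.finite(lo) && is.finite(hi)) {
    L <- lo
    R <- hi
  } else {
    u <- stats::runif(1)
    L <- x0 - w * u
    R <- L + w
    k <- max_steps
    while (k > 0 && L > lo && logf(max(L, lo)) > z) {
      L <- L - w
      k <- k - 1
    }
    k <- max_steps
    while (k > 0 && R < hi && logf(min(R, hi)) > z) {
      R <- R + w
      k <- k - 1
    }
    L <- max(L, lo)
    R <- min(R, hi)
  }
  for (i in seq_len(100)) {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

# draw from N(mean, diag(var)) conditioned on C x = 0 (C full row rank)
draw_constrained_normal <- function(mean_post, var_post, C = NULL) {
  z <- stats::rnorm(length(mean_post), mean_post, sqrt(var_post))
  if (is.null(C)) return(z)
  VC <- var_post * t(C)
  M <- C %*% VC
  drop(z - VC %*% solve(M, C %*% z))
}

# sum-to-zero constraint rows for a term laid out over `lens` (first
# dimension fastest); margins over each dimension, reduced to full rank
sum_zero_constraints <- function(lens) {
  L <- prod(lens)
  if (length(lens) == 1) {
    C <- matrix(1, 1, L)
  } else {
    g <- rev(expand.grid(rev(lapply(lens, seq_len)), KEEP.OUT.ATTRS = FALSE))
    rows <- list()
    for (d in seq_along(lens)) {
      # for each level combination of the other dims, sum over dim d
      other <- g[, -d, drop = FALSE]
      key <- do.call(paste, c(other, sep = "."))
      uk <- unique(key)
      rows[[d]] <- t(vapply(uk, function(k) as.numeric(key == k),
                            numeric(L)))
    }
    C <- do.call(rbind, rows)
  }
  q <- qr(t(C))
  C[q$pivot[seq_len(q$rank)], , drop = FALSE]
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# group sums over integer group ids, returning a dense length-n vector
# (rowsum drops empty groups, which would misalign level indexing)
rowsum_dense <- function(x, g, n) {
  rs <- rowsum(x, g)
  out <- numeric(n)
  out[as.integer(rownames(rs))] <- rs
  out
}

# half-normal-prior scale update given ss = sum of squared innovations on
# N degrees of freedom
slice_scale <- function(x0, ss, N, prior_sd, w = NULL) {
  logf <- function(s) {
    if (s <= 0) return(-Inf)
    -N * log(s) - ss / (2 * s^2) + ldens_half_normal(s, prior_sd)
  }
  if (is.null(w)) w <- max(x0, 0.02)
  slice1(x0, logf, w = w, lo = 1e-9, hi = Inf)
}

# ---- fit setup -----------------------------------------------------------

fit_setup <- function(grid, terms, datasets, priors, exposures) {
  design <- build_design(terms, grid)
  nC <- grid$n_cells
  cells <- grid_cells(grid)

  info <- purrr::imap(design, function(d, nm) {
    p <- d$prior
    ti <- list(idx = d$idx, n_levels = d$n_levels, labels = d$labels,
               dims = d$dims, prior = p)
    if (inherits(p, "prior_damped_trend")) {
      ti$type <- "trend"
      ti$n_time <- d$n_time
      ti$n_chain <- d$n_chain
      ti$C <- NULL
    } else if (length(d$dims) == 0) {
      ti$type <- "intercept"
      ti$C <- NULL
    } else {
      ti$type <- if (inherits(p, "prior_hier_normal")) "hier" else "normal"
      lens <- lengths(grid$dims)[d$dims]
      ti$C <- sum_zero_constraints(lens)
      ti$df <- d$n_levels - nrow(ti$C)
    }
    ti
  })

  # exposures
  n_true <- NULL
  latent_needed <- any(vapply(datasets, function(d)
    d$kind %in% c("survey", "admin"), logical(1)))
  if (latent_needed) {
    if (is.null(exposures)) {
      stop("survey/admin data models need `exposures` (true population ",
           "at risk per cell)", call. = FALSE)
    }
    exposures <- tibble::as_tibble(exposures)
    if (!"n_true" %in% names(exposures)) {
      stop("`exposures` needs an `n_true` column", call. = FALSE)
    }
    idx <- cells_from_labels(grid, exposures)
    if (anyDuplicated(idx) > 0) stop("duplicate exposure cells",
                                     call. = FALSE)
    n_true <- rep(NA_real_, nC)
    n_true[idx] <- exposures$n_true
    if (any(n_true[cells$year <= grid$data_until] <= 0, na.rm = TRUE) ||
        anyNA(n_true[cells$year <= grid$data_until])) {
      stop("exposures must be positive and cover every observed-span cell",
           call. = FALSE)
    }
  }

  # binomial observations -> per-cell sums
  bin_a <- numeric(nC)
  bin_b <- numeric(nC)
  # survey (normal) observations
  obs_val <- numeric(0)
  obs_kappa <- numeric(0)
  pair_obs <- integer(0)
  pair_cell <- integer(0)
  admin <- list()
  for (ds in datasets) {
    map <- dataset_cell_map(ds, grid)
    if (ds$kind == "binomial") {
      bin_a[map$cell_index] <- bin_a[map$cell_index] + ds$data$y_eff
      bin_b[map$cell_index] <- bin_b[map$cell_index] + ds$data$n_eff
    } else if (ds$kind == "survey") {
      off <- length(obs_val)
      obs_val <- c(obs_val, ds$data$value)
      obs_kappa <- c(obs_kappa, ds$data$sd)
      pair_obs <- c(pair_obs, map$obs_index + off)
      pair_cell <- c(pair_cell, map$cell_index)
    } else if (ds$kind == "admin") {
      if (any(ds$data$value >= n_true[map$cell_index])) {
        stop("admin count at or above the exposure for dataset '",
             ds$name, "'", call. = FALSE)
      }
      ages <- as.character(grid$dims$age)
      admin[[ds$name]] <- list(
        cell = map$cell_index,
        logv = log(ds$data$value),
        age_idx = match(as.character(ds$data$age), ages),
        ages = ages,
        n_ages = length(ages)
      )
    }
  }

  active <- sort(unique(c(pair_cell, unlist(lapply(admin, `[[`, "cell")))))
  act_pos <- rep(NA_integer_, nC)
  act_pos[active] <- seq_along(active)

  # CSR map active cell -> survey obs ids (0-based) for the C++ sweep
  if (length(pair_obs)) {
    ord <- order(act_pos[pair_cell], pair_obs)
    po <- pair_obs[ord]
    pc <- act_pos[pair_cell][ord]
    cnt <- tabulate(pc, length(active))
    obs_ptr <- c(0L, cumsum(cnt))
    obs_idx0 <- as.integer(po - 1L)
  } else {
    obs_ptr <- integer(length(active) + 1)
    obs_idx0 <- integer(0)
  }

  # admin attributes per active cell (at most one admin source per cell)
  has_admin <- logical(length(active))
  admin_logv <- numeric(length(active))
  admin_age <- rep(NA_integer_, length(active))
  admin_ds_of_cell <- rep(NA_integer_, length(active))
  admin_gidx <- rep(NA_integer_, length(active)) # into concatenated gammas
  goff <- 0L
  for (k in seq_along(admin)) {
    a <- admin[[k]]
    pos <- act_pos[a$cell]
    if (any(has_admin[pos])) {
      stop("two admin datasets observe the same cell", call. = FALSE)
    }
    has_admin[pos] <- TRUE
    admin_logv[pos] <- a$logv
    admin_age[pos] <- a$age_idx
    admin_ds_of_cell[pos] <- k
    admin_gidx[pos] <- goff + a$age_idx
    goff <- goff + a$n_ages
  }

  # cells carrying any likelihood term; all other cells are marginalised
  # out of the effect/sigma updates (their logit-prevalences carry no
  # information and are redrawn by exact Gibbs each iteration)
  dat <- which(bin_b > 0 | seq_len(nC) %in% active)
  for (nm in names(info)) {
    idx_dat <- info[[nm]]$idx[dat]
    info[[nm]]$idx_dat <- idx_dat
    info[[nm]]$fidx_dat <- factor(idx_dat,
                                  levels = seq_len(info[[nm]]$n_levels))
    info[[nm]]$m_dat <- tabulate(idx_dat, info[[nm]]$n_levels)
  }
  pair_fac <- if (length(pair_obs)) {
    factor(pair_obs, levels = seq_along(obs_val))
  }
  # per-observation member cells and the set of observations sharing any
  # member (for the collective group-shift move)
  obs_members <- obs_aff <- list()
  if (length(pair_obs)) {
    obs_members <- split(pair_cell, factor(pair_obs,
                                           levels = seq_along(obs_val)))
    cell_obs <- split(pair_obs, factor(pair_cell))
    obs_aff <- lapply(obs_members, function(cells) {
      sort(unique(unlist(cell_obs[as.character(cells)])))
    })
  }

  # crude initial rates: survey observations spread over their cells,
  # binomial observations directly, gaps filled by age-sex averages
  init_rate <- rep(NA_real_, nC)
  if (length(pair_obs)) {
    n_obs_tot <- rowsum_dense(n_true[pair_cell], pair_obs,
                              length(obs_val))
    r_obs <- pmin(pmax(obs_val / n_obs_tot, 1e-4), 1 - 1e-4)
    init_rate[pair_cell] <- r_obs[pair_obs]
  }
  has_bin <- bin_b > 0
  init_rate[has_bin] <- pmin(pmax(bin_a[has_bin] / bin_b[has_bin], 1e-4),
                             1 - 1e-4)
  # fill unobserved cells by extrapolating a per-group linear trend of
  # the survey-implied logits over years (falling back to group means),
  # so cells covered only by biased sources start near the trend the
  # unbiased sources imply rather than at a historical average
  init_logit <- logit(init_rate)
  grpdims <- intersect(c("age", "sex", "country"), names(grid$dims))
  grp <- do.call(paste, cells[grpdims])
  overall <- mean(init_logit, na.rm = TRUE)
  if (!is.finite(overall)) overall <- logit(0.1)
  for (g in unique(grp)) {
    sel <- grp == g
    v <- init_logit[sel]
    yr <- cells$year[sel]
    known <- is.finite(v)
    if (!any(known)) {
      init_logit[sel][!known] <- overall
    } else if (length(unique(yr[known])) >= 2) {
      fitg <- stats::lm.fit(cbind(1, yr[known]), v[known])
      pred <- cbind(1, yr) %*% fitg$coefficients
      init_logit[sel][!known] <- pred[!known]
    } else {
      init_logit[sel][!known] <- mean(v[known])
    }
  }

  su <- list(grid = grid, design = design, info = info, n_cells = nC,
       cells = cells, n_true = n_true, priors = priors,
       bin_a = bin_a, bin_b = bin_b, dat = dat,
       free = setdiff(seq_len(nC), dat),
       act_in_dat = match(active, dat),
       obs_val = obs_val, obs_kappa = obs_kappa,
       pair_obs = pair_obs, pair_cell = pair_cell, pair_fac = pair_fac,
       active = active, act_pos = act_pos,
       obs_ptr = obs_ptr, obs_idx0 = obs_idx0,
       admin = admin, has_admin = has_admin, admin_logv = admin_logv,
       admin_age = admin_age, admin_ds_of_cell = admin_ds_of_cell,
       admin_gidx = admin_gidx, init_logit = init_logit,
       obs_members = obs_members, obs_aff = obs_aff,
       # fixed transfer coefficient for the variance-swap move (must not
       # depend on the chain state, or the move loses reversibility)
       swap_kbar = if (any(has_admin)) {
         mean((1 - inv_logit(init_logit[active[has_admin]]))^2)
       } else 1)

  # precomputation for the bias-trend translation move: per admin source
  # and age, the cells of that age over the admin window, the window's
  # time indices, the (frozen) log-slope coefficient linking a logit
  # shift to the implied log-count shift, and the survey observations
  # whose aggregates those cells feed
  at_term <- names(info)[vapply(info, function(ti) {
    identical(ti$dims, c("age", grid$time_dim)) && ti$type == "trend"
  }, logical(1))]
  if (length(admin) >= 1 && length(at_term) == 1 && "age" %in%
      names(grid$dims)) {
    cell_obs_all <- if (length(pair_obs)) split(pair_obs, pair_cell)
    su$bias_move <- purrr::imap(admin, function(a, dsn) {
      yrs <- sort(unique(cells$year[a$cell]))
      tw <- match(yrs, grid$dims$year)
      purrr::map(seq_len(a$n_ages), function(ai) {
        cls <- which(cells$age == a$ages[ai] & cells$year %in% yrs)
        obs <- sort(unique(unlist(cell_obs_all[as.character(cls)])))
        list(age = ai, cells = cls, tw = tw,
             cslope = mean(1 - inv_logit(init_logit[cls])),
             obs = obs)
      })
    })
    su$bias_term <- at_term
  }
  su
}

# ---- chain state ---------------------------------------------------------

init_state <- function(su, jitter = TRUE) {
  nC <- su$n_cells
  # start logit-prevalences at survey-implied crude rates (gaps filled by
  # age-sex averages), so biased sources begin with the bias in the bias
  # parameters rather than in the prevalences
  theta <- su$init_logit + stats::rnorm(nC, 0, 0.1)
  pbar_logit <- mean(su$init_logit)
  effects <- purrr::map(su$info, function(ti) {
    b <- stats::rnorm(ti$n_levels, 0, if (jitter) 0.01 else 0)
    if (ti$type == "intercept") b <- b + pbar_logit
    if (!is.null(ti$C)) b <- b - drop(t(ti$C) %*%
      solve(ti$C %*% t(ti$C), ti$C %*% b))
    b
  })
  trend <- purrr::map(su$info[purrr::map_chr(su$info, "type") == "trend"],
    function(ti) {
      list(alpha = matrix(0, ti$n_chain, ti$n_time + 1),
           delta = matrix(0, ti$n_chain, ti$n_time + 1),
           hypers = trend_hypers(
             stats::runif(1, 0.02, 0.1), stats::runif(1, 0.02, 0.1),
             stats::runif(1, 0.01, 0.05), stats::runif(1, 0.85, 0.95)))
    })
  hier_tau <- purrr::map(
    su$info[purrr::map_chr(su$info, "type") == "hier"],
    function(ti) stats::runif(1, 0.2, 0.5))
  y <- NULL
  if (length(su$active)) {
    p <- inv_logit(theta[su$active])
    n <- su$n_true[su$active]
    y <- pmin(pmax(n * p, 1e-6 * n), (1 - 1e-6) * n)
  }
  gamma0 <- purrr::map(su$admin, function(a) {
    r <- a$logv - log(su$n_true[a$cell] * inv_logit(theta[a$cell]))
    g <- tapply(r, factor(a$age_idx, levels = seq_len(a$n_ages)), mean)
    g[is.na(g)] <- 0
    as.numeric(g) + stats::rnorm(a$n_ages, 0, 0.02)
  })
  st <- list(theta = theta, effects = effects, trend = trend,
             hier_tau = hier_tau, sigma = stats::runif(1, 0.05, 0.15),
             y = y,
             gamma = gamma0,
             sigma_y = purrr::map(su$admin, function(a)
               stats::runif(1, 0.1, 0.3)),
             sigma_gamma = purrr::map(su$admin, function(a)
               stats::runif(1, 0.3, 0.7)))
  st$mu <- linear_predictor(st$effects, su$design)
  st$lstep_theta <- rep(log(0.5), nC)
  st$lstep_y <- if (length(su$active)) rep(log(0.5), length(su$active))
  st$lstep_joint <- if (length(su$active)) rep(log(0.1), length(su$active))
  st$lstep_swap <- log(2e-3)
  st$lstep_group <- rep(log(0.05), length(su$obs_members))
  st$lstep_bias <- purrr::map(su$bias_move %||% list(),
                              function(b) rep(log(0.05), length(b)))
  st
}

# ---- per-iteration updates ----------------------------------------------

# Metropolis update of logit-prevalences at data-carrying cells; the
# cells are conditionally independent given the latent counts, so the
# elementwise vectorised accept/reject is exact.
update_theta_mh <- function(st, su, adapt_rate) {
  i <- su$dat
  if (!length(i)) return(st)
  a <- su$bin_a[i]
  b <- su$bin_b[i]
  if (length(su$active)) {
    pos <- su$act_in_dat
    a[pos] <- a[pos] + st$y
    b[pos] <- b[pos] + su$n_true[su$active]
  }
  mu <- st$mu[i]
  sg <- st$sigma
  thi <- st$theta[i]
  prop <- thi + exp(st$lstep_theta[i]) * stats::rnorm(length(i))
  logr <- (-(prop - mu)^2 + (thi - mu)^2) / (2 * sg^2) +
    a * (prop - thi) - b * (softplus(prop) - softplus(thi))
  acc <- log(stats::runif(length(i))) < logr
  thi[acc] <- prop[acc]
  st$theta[i] <- thi
  if (adapt_rate > 0) {
    st$lstep_theta[i] <- st$lstep_theta[i] + adapt_rate * (acc - 0.44)
  }
  st
}

# exact Gibbs draw of logit-prevalences at cells with no likelihood term
# (data gaps and forecast years): theta ~ N(mu, sigma^2)
draw_free_theta <- function(st, su) {
  free <- su$free
  st$theta[free] <- stats::rnorm(length(free), st$mu[free], st$sigma)
  st
}

update_y <- function(st, su, adapt_rate, joint = TRUE) {
  if (!length(su$active)) return(st)
  S <- numeric(length(su$obs_val))
  if (length(su$pair_obs)) {
    yfull <- numeric(su$n_cells)
    yfull[su$active] <- st$y
    S <- rowsum_dense(yfull[su$pair_cell], su$pair_obs,
                      length(su$obs_val))
  }
  gam_cell <- numeric(length(su$active))
  sy_cell <- rep(1, length(su$active))
  if (length(su$admin)) {
    w <- which(su$has_admin)
    gam_cell[w] <- unlist(st$gamma)[su$admin_gidx[w]]
    sy_cell[w] <- unlist(st$sigma_y)[su$admin_ds_of_cell[w]]
  }
  res <- y_sweep_cpp(st$y, su$n_true[su$active],
                     inv_logit(st$theta[su$active]),
                     su$obs_ptr, su$obs_idx0, su$obs_val, su$obs_kappa, S,
                     su$has_admin, su$admin_logv, gam_cell, sy_cell,
                     st$lstep_y)
  st$y <- res$y
  if (adapt_rate > 0) {
    st$lstep_y <- st$lstep_y + adapt_rate * (res$acc - 0.44)
  }
  # joint (theta, y) ridge sweep
  if (!joint) return(st)
  res2 <- theta_y_sweep_cpp(st$theta[su$active], st$mu[su$active],
                            st$sigma, st$y, su$n_true[su$active],
                            su$obs_ptr, su$obs_idx0, su$obs_val,
                            su$obs_kappa, res$S,
                            su$has_admin, su$admin_logv, gam_cell, sy_cell,
                            su$bin_a[su$active], su$bin_b[su$active],
                            st$lstep_joint)
  st$theta[su$active] <- res2$theta
  st$y <- res2$y
  if (adapt_rate > 0) {
    st$lstep_joint <- st$lstep_joint + adapt_rate * (res2$acc - 0.44)
  }
  st
}

# Conjugate Gibbs updates of the effect terms, conditioning on the
# logit-prevalences at data-carrying cells only (data-free cells are
# marginalised out exactly — they contribute no information about the
# effects and are redrawn afterwards by draw_free_theta()).
update_effects <- function(st, su) {
  sg2 <- st$sigma^2
  th_dat <- st$theta[su$dat]
  mu_dat <- st$mu[su$dat]
  for (nm in names(su$info)) {
    ti <- su$info[[nm]]
    if (ti$type == "trend") next # handled jointly in update_trends()
    b_old <- st$effects[[nm]]
    e <- th_dat - (mu_dat - b_old[ti$idx_dat])
    s <- if (length(e)) {
      rowsum_dense(e, ti$idx_dat, ti$n_levels)
    } else numeric(ti$n_levels)
    if (ti$type == "intercept") {
      pv <- ti$prior$sd^2
      post_v <- 1 / (ti$m_dat / sg2 + 1 / pv)
      post_m <- (s / sg2 + ti$prior$mean / pv) * post_v
      b_new <- stats::rnorm(1, post_m, sqrt(post_v))
    } else if (ti$type == "normal") {
      pv <- ti$prior$sd^2
      post_v <- 1 / (ti$m_dat / sg2 + 1 / pv)
      post_m <- (s / sg2 + ti$prior$mean / pv) * post_v
      b_new <- draw_constrained_normal(post_m, post_v, ti$C)
    } else { # hier
      pv <- st$hier_tau[[nm]]^2
      post_v <- 1 / (ti$m_dat / sg2 + 1 / pv)
      post_m <- (s / sg2) * post_v
      b_new <- draw_constrained_normal(post_m, post_v, ti$C)
    }
    st$effects[[nm]] <- b_new
    mu_dat <- mu_dat + (b_new - b_old)[ti$idx_dat]
    st$mu <- st$mu + (b_new - b_old)[ti$idx]
  }
  st
}

# Joint update of each time-bearing term: the trend levels beta are
# marginalised into the Kalman filter (pseudo-observation per chain and
# year = the cell-residual mean, with variance sigma^2/m + tau_beta^2;
# years with no data-carrying cells contribute no observation), the
# states (alpha, delta) are drawn by FFBS, and beta is then drawn from
# its exact conditional given states and data. Hyperparameters follow by
# slice sampling on the pooled innovations.
update_trends <- function(st, su, repeats = 2) {
  for (r in seq_len(repeats)) {
    st <- update_trends_once(st, su)
    st <- update_translations(st, su)
  }
  st
}

update_trends_once <- function(st, su) {
  sg2 <- st$sigma^2
  th_dat <- st$theta[su$dat]
  for (nm in names(st$trend)) {
    ti <- su$info[[nm]]
    tr <- st$trend[[nm]]
    h <- tr$hypers
    prior <- ti$prior
    Tn <- ti$n_time
    nc <- ti$n_chain
    b_old <- st$effects[[nm]]
    e <- th_dat - (st$mu[su$dat] - b_old[ti$idx_dat])
    s <- if (length(e)) rowsum_dense(e, ti$idx_dat, ti$n_levels) else
      numeric(ti$n_levels)
    m <- ti$m_dat
    smat <- matrix(s, nc, Tn)
    mmat <- matrix(m, nc, Tn)
    tb2 <- max(h$tau_beta^2, 1e-12)
    for (cc in seq_len(nc)) {
      mm <- mmat[cc, ]
      obs <- ifelse(mm > 0, smat[cc, ] / pmax(mm, 1), NA_real_)
      ovar <- ifelse(mm > 0, sg2 / pmax(mm, 1) + tb2, Inf)
      sts <- ffbs_trend(obs, ovar, h, init_sd = prior$init_sd)
      tr$alpha[cc, ] <- sts$alpha
      tr$delta[cc, ] <- sts$delta
    }
    al <- tr$alpha
    de <- tr$delta
    # beta | states, data
    pm <- as.vector(al[, -1, drop = FALSE])
    post_v <- 1 / (m / sg2 + 1 / tb2)
    post_m <- (s / sg2 + pm / tb2) * post_v
    b_new <- stats::rnorm(ti$n_levels, post_m, sqrt(post_v))
    st$effects[[nm]] <- b_new
    st$mu <- st$mu + (b_new - b_old)[ti$idx]
    bmat <- matrix(b_new, nc, Tn)
    # hyperparameter slices, innovations pooled across chains
    v <- bmat - al[, -1, drop = FALSE]
    h$tau_beta <- slice_scale(h$tau_beta, sum(v^2), length(v),
                              prior$tau_beta$sd)
    v <- al[, -1, drop = FALSE] - al[, -(Tn + 1), drop = FALSE] -
      de[, -(Tn + 1), drop = FALSE]
    h$tau_alpha <- slice_scale(h$tau_alpha, sum(v^2), length(v),
                               prior$tau_alpha$sd)
    dlag <- de[, -(Tn + 1), drop = FALSE]
    dnow <- de[, -1, drop = FALSE]
    v <- dnow - h$phi * dlag
    h$tau_delta <- slice_scale(h$tau_delta, sum(v^2), length(v),
                               prior$tau_delta$sd)
    td2 <- max(h$tau_delta^2, 1e-12)
    logf_phi <- function(p) {
      ldens_scaled_beta(p, prior$phi) - sum((dnow - p * dlag)^2) / (2 * td2)
    }
    h$phi <- slice1(h$phi, logf_phi, lo = prior$phi$lo, hi = prior$phi$hi)
    tr$hypers <- h
    st$trend[[nm]] <- tr
  }
  st
}

# Exact Gibbs translation moves along the additively aliased directions
# (intercept vs the year trend level; each time interaction's common
# level vs the year trend level). The likelihood is invariant along these
# directions — every cell contains exactly one level of each term — so the
# conditional for the shift is Gaussian, determined by the initial-state
# and intercept priors alone. These moves remove the slow random walk
# that plain one-term-at-a-time Gibbs exhibits along aliased directions.
update_translations <- function(st, su) {
  types <- purrr::map_chr(su$info, "type")
  trend_nms <- names(st$trend)
  year_nm <- trend_nms[vapply(trend_nms,
                              function(nm) su$info[[nm]]$n_chain == 1,
                              logical(1))]
  if (length(year_nm) != 1) return(st)
  year_nm <- year_nm[1]
  s0y2 <- su$info[[year_nm]]$prior$init_sd^2
  shift <- function(st, nm, d) {
    st$trend[[nm]]$alpha <- st$trend[[nm]]$alpha + d
    st$effects[[nm]] <- st$effects[[nm]] + d
    st
  }
  int_nm <- names(types)[types == "intercept"]
  if (length(int_nm) == 1) {
    si2 <- su$info[[int_nm]]$prior$sd^2
    i0 <- st$effects[[int_nm]]
    a0 <- st$trend[[year_nm]]$alpha[1, 1]
    prec <- 1 / si2 + 1 / s0y2
    d <- stats::rnorm(1, (a0 / s0y2 - i0 / si2) / prec, sqrt(1 / prec))
    st$effects[[int_nm]] <- i0 + d
    st <- shift(st, year_nm, -d)
  }
  for (nm in setdiff(trend_nms, year_nm)) {
    s0t2 <- su$info[[nm]]$prior$init_sd^2
    nc <- su$info[[nm]]$n_chain
    a0c <- st$trend[[nm]]$alpha[, 1]
    ay0 <- st$trend[[year_nm]]$alpha[1, 1]
    prec <- nc / s0t2 + 1 / s0y2
    d <- stats::rnorm(1, (-sum(a0c) / s0t2 + ay0 / s0y2) / prec,
                      sqrt(1 / prec))
    st <- shift(st, nm, d)
    st <- shift(st, year_nm, -d)
    # per-chain shifts against the matching main effect (sum-to-zero on
    # the shift, so the constrained main effect stays on its subspace)
    main_dim <- setdiff(su$info[[nm]]$dims, su$grid$time_dim %||% "year")
    main_nm <- names(su$info)[vapply(su$info, function(ti) {
      identical(ti$dims, main_dim) && ti$type %in% c("normal", "hier")
    }, logical(1))]
    if (length(main_nm) == 1 && nc > 1) {
      ti_m <- su$info[[main_nm]]
      v_b <- if (ti_m$type == "hier") st$hier_tau[[main_nm]]^2 else
        ti_m$prior$sd^2
      b <- st$effects[[main_nm]]
      a0c <- st$trend[[nm]]$alpha[, 1]
      prec <- 1 / v_b + 1 / s0t2
      mean_d <- (-b / v_b + a0c / s0t2) / prec
      dvec <- draw_constrained_normal(mean_d, rep(1 / prec, nc),
                                      matrix(1, 1, nc))
      st$effects[[main_nm]] <- b + dvec
      st$trend[[nm]]$alpha <- st$trend[[nm]]$alpha - dvec
      bm <- matrix(st$effects[[nm]], nc)
      st$effects[[nm]] <- as.vector(bm - dvec)
    }
  }
  st
}

update_hier_tau <- function(st, su) {
  for (nm in names(st$hier_tau)) {
    ti <- su$info[[nm]]
    b <- st$effects[[nm]]
    if (ti$df == 0) { # singleton dimension: prior draw
      st$hier_tau[[nm]] <- draw_prior(ti$prior$tau_prior)
      next
    }
    st$hier_tau[[nm]] <- slice_scale(st$hier_tau[[nm]], sum(b^2), ti$df,
                                     ti$prior$tau_prior$sd)
  }
  st
}

# sigma conditions on data-carrying cells only (data-free cells are
# marginalised exactly, as in update_effects)
update_sigma <- function(st, su) {
  ss <- sum((st$theta[su$dat] - st$mu[su$dat])^2)
  st$sigma <- slice_scale(st$sigma, ss, length(su$dat),
                          su$priors$sigma$sd)
  st
}

# Interweaved non-centered sigma update (ASIS): holding the standardised
# residuals z = (theta - mu)/sigma fixed, slice-sample sigma along the
# curve theta(sigma) = mu + sigma z, carrying each latent count along the
# binomial mean (a volume-preserving shear). Alternated with the centered
# update and the variance-swap move, this lets sigma traverse the funnel
# between "field locked to the predictor" and "field tracking the data".
update_sigma_ncp <- function(st, su) {
  i <- su$dat
  if (!length(i)) return(st)
  s0 <- st$sigma
  mu <- st$mu[i]
  z <- (st$theta[i] - mu) / max(s0, 1e-12)
  apos <- su$act_in_dat
  n_act <- su$n_true[su$active]
  p0_act <- inv_logit(mu[apos] + s0 * z[apos])
  y0 <- st$y
  bb <- which(su$bin_b[i] > 0)
  w <- which(su$has_admin)
  gam <- if (length(w)) unlist(st$gamma)[su$admin_gidx[w]]
  sy <- if (length(w)) unlist(st$sigma_y)[su$admin_ds_of_cell[w]]
  logf <- function(s) {
    if (s <= 0) return(-Inf)
    th <- mu + s * z
    lp <- ldens_half_normal(s, su$priors$sigma$sd)
    if (length(bb)) {
      lp <- lp + sum(su$bin_a[i][bb] * th[bb] -
                       su$bin_b[i][bb] * softplus(th[bb]))
    }
    if (length(su$active)) {
      p <- inv_logit(th[apos])
      y <- y0 + n_act * (p - p0_act)
      if (any(y <= 0 | y >= n_act) || any(p <= 0 | p >= 1)) return(-Inf)
      lp <- lp + sum(-lgamma(y + 1) - lgamma(n_act - y + 1) +
                       y * log(p) + (n_act - y) * log1p(-p))
      if (length(su$pair_obs)) {
        yf <- numeric(su$n_cells)
        yf[su$active] <- y
        S <- rowsum_dense(yf[su$pair_cell], su$pair_obs,
                          length(su$obs_val))
        lp <- lp + sum(stats::dnorm(su$obs_val, S, su$obs_kappa,
                                    log = TRUE))
      }
      if (length(w)) {
        lp <- lp + sum(stats::dnorm(su$admin_logv[w], log(y[w]) + gam,
                                    sy, log = TRUE))
      }
    }
    lp
  }
  s_new <- slice1(s0, logf, w = max(s0 / 2, 0.02), lo = 1e-9, hi = Inf)
  if (s_new != s0) {
    st$sigma <- s_new
    st$theta[i] <- mu + s_new * z
    if (length(su$active)) {
      p <- inv_logit(st$theta[i][apos])
      st$y <- y0 + n_act * (p - p0_act)
    }
  }
  st
}

# Variance-swap orbit slice: transfers dispersion between the cell-level
# noise sd sigma and the administrative noise sd sigma_y along the
# softly identified direction sigma_y^2 + c^2 sigma^2 ~ const. Along the
# orbit, each administrative cell's logit-prevalence is carried through
# the affine map of its linearised conditional Gaussian (mean and
# variance as functions of sigma, sigma_y, linearised at the current
# predictor), other data-carrying cells are residual-scaled, and latent
# counts follow the binomial mean. The family is a one-parameter group
# for the coefficients frozen within the move, so slice sampling along
# the orbit with the exact joint density (plus the affine volume terms)
# is valid; the linearisation only shapes the orbit. This lets a single
# draw cross the near-flat ridge between "variation is real" and
# "variation is administrative noise" in either direction — including
# rebuilding data-tracking deviations when leaving the small-sigma
# corner, which residual scaling alone cannot do.
update_variance_swap <- function(st, su, adapt_rate = 0) {
  if (!length(su$admin) || !length(su$active)) return(st)
  w_all <- which(su$has_admin)
  if (!length(w_all)) return(st)
  ds_k <- su$admin_ds_of_cell[w_all][1]
  wk <- w_all[su$admin_ds_of_cell[w_all] == ds_k] # active positions
  sy <- st$sigma_y[[ds_k]]
  s <- st$sigma
  if (s^2 <= 1e-10 || sy^2 <= 1e-10) return(st) # degenerate orbit
  i <- su$dat
  apos <- su$act_in_dat
  adm_dat <- apos[wk] # positions of this source's admin cells within dat
  oth_dat <- setdiff(seq_along(i), adm_dat)
  mu_d <- st$mu[i]
  th_d <- st$theta[i]
  n_act <- su$n_true[su$active]
  p0_act <- inv_logit(th_d[apos])
  y0 <- st$y
  bb <- which(su$bin_b[i] > 0)
  gam_all <- unlist(st$gamma)[su$admin_gidx[w_all]]
  sy_all <- unlist(st$sigma_y)[su$admin_ds_of_cell[w_all]]
  gam_k <- gam_all[match(wk, w_all)]
  pr <- su$priors$admin_sigma_y
  # linearisation of the admin likelihood at the current predictor
  mu_adm <- mu_d[adm_dat]
  p_mu <- inv_logit(mu_adm)
  ci <- pmax(1 - p_mu, 1e-6)
  K <- ci^2
  kbar <- mean(K)
  zeta <- mu_adm + (su$admin_logv[wk] - gam_k -
                      log(n_act[wk] * p_mu)) / ci
  v_of <- function(s2, sy2) 1 / (1 / s2 + K / sy2)
  m_of <- function(s2, sy2, v) v * (mu_adm / s2 + K * zeta / sy2)
  v0 <- v_of(s^2, sy^2)
  m0 <- m_of(s^2, sy^2, v0)
  S_needed <- length(su$pair_obs) > 0
  lb <- function(y, p) {
    -lgamma(y + 1) - lgamma(n_act - y + 1) + y * log(p) +
      (n_act - y) * log1p(-p)
  }
  state_of <- function(u) {
    s2n <- s^2 - u
    sy2n <- sy^2 + kbar * u
    if (s2n <= 1e-12 || sy2n <= 1e-12) return(NULL)
    sn <- sqrt(s2n)
    syn <- sqrt(sy2n)
    vn <- v_of(s2n, sy2n)
    mn <- m_of(s2n, sy2n, vn)
    th_new <- mu_d + (sn / s) * (th_d - mu_d)
    th_new[adm_dat] <- mn + sqrt(vn / v0) * (th_d[adm_dat] - m0)
    p_new <- inv_logit(th_new[apos])
    y_new <- y0 + n_act * (p_new - p0_act)
    if (any(y_new <= 0 | y_new >= n_act) ||
        any(p_new <= 0 | p_new >= 1)) return(NULL)
    list(sn = sn, syn = syn, vn = vn, th = th_new, p = p_new, y = y_new)
  }
  logg <- function(u) {
    xs <- state_of(u)
    if (is.null(xs)) return(-Inf)
    d <- ldens_half_normal(xs$sn, su$priors$sigma$sd) +
      log(s / xs$sn) + log(sy / xs$syn) + # (sigma, sigma_y) volume terms
      0.5 * sum(log(xs$vn / v0)) +        # admin-cell affine volume
      sum(stats::dnorm(xs$th[adm_dat], mu_adm, xs$sn, log = TRUE))
    if (inherits(pr, "prior_scaled_inv_chisq")) {
      d <- d + ldens_scaled_inv_chisq(xs$syn^2, pr$df, pr$scale2) +
        log(xs$syn)
    } else {
      d <- d + ldens_half_normal(xs$syn, pr$sd)
    }
    if (length(bb)) {
      d <- d + sum(su$bin_a[i][bb] * xs$th[bb] -
                     su$bin_b[i][bb] * softplus(xs$th[bb]))
    }
    d <- d + sum(lb(xs$y, xs$p))
    if (S_needed) {
      yf <- numeric(su$n_cells)
      yf[su$active] <- xs$y
      S <- rowsum_dense(yf[su$pair_cell], su$pair_obs,
                        length(su$obs_val))
      d <- d + sum(stats::dnorm(su$obs_val, S, su$obs_kappa, log = TRUE))
    }
    syc <- sy_all
    syc[match(wk, w_all)] <- xs$syn
    d + sum(stats::dnorm(su$admin_logv[w_all],
                         log(xs$y[w_all]) + gam_all, syc, log = TRUE))
  }
  u_new <- slice1(0, logg, lo = -(sy^2 - 1e-12) / kbar,
                  hi = s^2 - 1e-12)
  if (u_new != 0) {
    xs <- state_of(u_new)
    if (!is.null(xs)) {
      st$sigma <- xs$sn
      st$sigma_y[[ds_k]] <- xs$syn
      st$theta[i] <- xs$th
      st$y <- xs$y
    }
  }
  st
}

# Collective shift of all member cells of each aggregated survey
# observation: theta of every member moves by a common d (latent counts
# carried along the binomial mean), so the observation's aggregate level
# mixes in one step instead of diffusing through per-cell moves. Cells
# shared with other observations are handled by recomputing every
# affected aggregate exactly.
update_group_shift <- function(st, su, adapt_rate) {
  n_obs <- length(su$obs_members)
  if (!n_obs) return(st)
  yfull <- numeric(su$n_cells)
  yfull[su$active] <- st$y
  gam_full <- sy_full <- rep(NA_real_, su$n_cells)
  w <- which(su$has_admin)
  if (length(w)) {
    gam_full[su$active][w] <- unlist(st$gamma)[su$admin_gidx[w]]
    sy_full[su$active][w] <- unlist(st$sigma_y)[su$admin_ds_of_cell[w]]
  }
  logv_full <- rep(NA_real_, su$n_cells)
  if (length(w)) logv_full[su$active][w] <- su$admin_logv[w]
  s2 <- 2 * st$sigma^2
  acc <- logical(n_obs)
  for (o in seq_len(n_obs)) {
    cells <- su$obs_members[[o]]
    d <- exp(st$lstep_group[o]) * stats::rnorm(1)
    th <- st$theta[cells]
    thp <- th + d
    n <- su$n_true[cells]
    p <- inv_logit(th)
    pp <- inv_logit(thp)
    y <- yfull[cells]
    yp <- y + n * (pp - p)
    if (any(yp <= 0 | yp >= n) || any(pp <= 0 | pp >= 1)) {
      if (adapt_rate > 0) {
        st$lstep_group[o] <- st$lstep_group[o] - adapt_rate * 0.3
      }
      next
    }
    lr <- sum((-(thp - st$mu[cells])^2 + (th - st$mu[cells])^2) / s2) +
      sum(-lgamma(yp + 1) - lgamma(n - yp + 1) + yp * log(pp) +
            (n - yp) * log1p(-pp)) -
      sum(-lgamma(y + 1) - lgamma(n - y + 1) + y * log(p) +
            (n - y) * log1p(-p))
    adm <- which(!is.na(gam_full[cells]))
    if (length(adm)) {
      ci <- cells[adm]
      lr <- lr + sum(stats::dnorm(logv_full[ci], log(yp[adm]) +
                                    gam_full[ci], sy_full[ci],
                                  log = TRUE) -
                       stats::dnorm(logv_full[ci], log(y[adm]) +
                                      gam_full[ci], sy_full[ci],
                                    log = TRUE))
    }
    aff <- su$obs_aff[[o]]
    S_old <- vapply(aff, function(a) sum(yfull[su$obs_members[[a]]]), 0)
    yfull[cells] <- yp
    S_new <- vapply(aff, function(a) sum(yfull[su$obs_members[[a]]]), 0)
    lr <- lr + sum(stats::dnorm(su$obs_val[aff], S_new,
                                su$obs_kappa[aff], log = TRUE) -
                     stats::dnorm(su$obs_val[aff], S_old,
                                  su$obs_kappa[aff], log = TRUE))
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      st$theta[cells] <- thp
      acc[o] <- TRUE
    } else {
      yfull[cells] <- y # roll back
    }
    if (adapt_rate > 0) {
      st$lstep_group[o] <- st$lstep_group[o] +
        adapt_rate * (acc[o] - 0.35)
    }
  }
  st$y <- yfull[su$active]
  st
}

# Bias-trend translation slice: for one age, shift the age-time trend
# level by d over the administrative window (carrying the cell
# logit-prevalences and latent counts along) while moving that age's
# bias term by the compensating -cslope * d (cslope frozen at setup so
# the family is a one-parameter group). Slice sampling along this orbit
# traverses the softly identified direction "real trend level vs
# administrative bias" in one draw; its posterior curvature comes from
# the trend-smoothness boundary terms and the survey overlap years,
# which are exactly the terms evaluated here (translations and
# binomial-mean shears have unit Jacobian).
update_bias_swap <- function(st, su, adapt_rate = 0) {
  if (is.null(su$bias_move)) return(st)
  tnm <- su$bias_term
  ti <- su$info[[tnm]]
  nA <- ti$n_chain
  Tn <- ti$n_time
  for (k in seq_along(su$bias_move)) {
    a <- su$admin[[k]]
    sy <- st$sigma_y[[k]]
    sgam <- st$sigma_gamma[[k]]
    for (ai in seq_along(su$bias_move[[k]])) {
      bm <- su$bias_move[[k]][[ai]]
      cls <- bm$cells
      act <- su$act_pos[cls]
      av <- which(!is.na(act))
      n <- su$n_true[cls[av]]
      th0 <- st$theta[cls]
      p0 <- inv_logit(th0[av])
      y0 <- st$y[act[av]]
      tr <- st$trend[[tnm]]
      h <- tr$hypers
      al <- tr$alpha[bm$age, ]
      de <- tr$delta[bm$age, ]
      tw <- bm$tw
      t0 <- tw[1]
      t1 <- tw[length(tw)]
      ta <- max(h$tau_alpha, 1e-9)
      g0 <- st$gamma[[k]][ai]
      sel_a <- which(a$age_idx == ai)
      m_pos <- match(a$cell[sel_a], cls[av])
      yfull <- NULL
      if (length(bm$obs)) {
        yfull <- numeric(su$n_cells)
        yfull[su$active] <- st$y
      }
      logg <- function(d) {
        thn <- th0 + d
        pn <- inv_logit(thn[av])
        yn <- y0 + n * (pn - p0)
        if (any(yn <= 0 | yn >= n) || any(pn <= 0 | pn >= 1)) return(-Inf)
        lr <- stats::dnorm(al[t0 + 1] + d - al[t0] - de[t0], 0, ta,
                           log = TRUE)
        if (t1 < Tn) {
          lr <- lr + stats::dnorm(al[t1 + 2] - al[t1 + 1] - d -
                                    de[t1 + 1], 0, ta, log = TRUE)
        }
        gn <- g0 - bm$cslope * d
        lr <- lr + stats::dnorm(gn, 0, sgam, log = TRUE) +
          sum(-lgamma(yn + 1) - lgamma(n - yn + 1) + yn * log(pn) +
                (n - yn) * log1p(-pn)) +
          sum(stats::dnorm(a$logv[sel_a], log(yn[m_pos]) + gn, sy,
                           log = TRUE))
        if (!is.null(yfull)) {
          yf <- yfull
          yf[cls[av]] <- yn
          for (o in bm$obs) {
            lr <- lr + stats::dnorm(su$obs_val[o],
                                    sum(yf[su$obs_members[[o]]]),
                                    su$obs_kappa[o], log = TRUE)
          }
        }
        lr
      }
      d_new <- slice1(0, logg, w = 0.1)
      if (d_new != 0) {
        st$theta[cls] <- th0 + d_new
        pn <- inv_logit(st$theta[cls][av])
        st$y[act[av]] <- y0 + n * (pn - p0)
        st$gamma[[k]][ai] <- g0 - bm$cslope * d_new
        st$trend[[tnm]]$alpha[bm$age, tw + 1] <-
          st$trend[[tnm]]$alpha[bm$age, tw + 1] + d_new
        lev <- bm$age + (tw - 1) * nA
        st$effects[[tnm]][lev] <- st$effects[[tnm]][lev] + d_new
        st$mu[cls] <- st$mu[cls] + d_new
      }
    }
  }
  st
}

update_admin_params <- function(st, su) {
  if (!length(su$admin)) return(st)
  yfull <- numeric(su$n_cells)
  yfull[su$active] <- st$y
  for (k in seq_along(su$admin)) {
    a <- su$admin[[k]]
    r <- a$logv - log(yfull[a$cell])
    sy <- st$sigma_y[[k]]
    sgam <- st$sigma_gamma[[k]]
    # gamma: conjugate normal per age
    s_a <- rowsum_dense(r, a$age_idx, a$n_ages)
    m_a <- tabulate(a$age_idx, a$n_ages)
    post_v <- 1 / (m_a / sy^2 + 1 / sgam^2)
    post_m <- (s_a / sy^2) * post_v
    gam <- stats::rnorm(a$n_ages, post_m, sqrt(post_v))
    # sigma_y: conjugate under scaled-inv-chisq, slice under half-normal
    rss <- sum((r - gam[a$age_idx])^2)
    pr <- su$priors$admin_sigma_y
    if (inherits(pr, "prior_scaled_inv_chisq")) {
      post_df <- pr$df + length(r)
      post_sc <- (pr$df * pr$scale2 + rss) / post_df
      sy <- sqrt(post_df * post_sc / stats::rchisq(1, post_df))
    } else {
      sy <- slice_scale(sy, rss, length(r), pr$sd)
    }
    sgam <- slice_scale(sgam, sum(gam^2), a$n_ages,
                        su$priors$admin_sigma_gamma$sd)
    st$gamma[[k]] <- gam
    st$sigma_y[[k]] <- sy
    st$sigma_gamma[[k]] <- sgam
  }
  st
}
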