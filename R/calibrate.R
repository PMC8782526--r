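#' Calibrate the administrative error-variance prior
#'
#' The administrative data model has error variance `sigma_y^2` on the log
#' scale. A plausible range for it can be derived from the administrative
#' direct prevalence estimates themselves: approximate log true prevalence
#' by the system model's main effects and interactions (with the age bias
#' absorbed into the age effect), fit by ordinary least squares, and take
#' the residual variance as a point estimate of `sigma_y^2`. The prior is
#' then a scaled inverse-chi-squared with that scale (rounded to 3
#' decimals) and a chosen degrees of freedom.
#'
#' `fit_bias_regression()` performs the least-squares step;
#' `calibrate_admin_prior()` wraps it into a prior specification and
#' reports the implied central 95% interval.
#'
#' @param direct_prev Tibble of administrative direct prevalence estimates
#'   with classification columns (`age`, `sex`, `region`, `urban`, `year`)
#'   and a positive `p` column.
#' @return `fit_bias_regression()` returns a list with `sigma2_hat`, the
#'   residual vector, the residual degrees of freedom, and the `lm` fit.
#' @export
fit_bias_regression <- function(direct_prev) {
  direct_prev <- tibble::as_tibble(direct_prev)
  if (!"p" %in% names(direct_prev)) {
    stop("`direct_prev` needs a `p` column", call. = FALSE)
  }
  if (any(direct_prev$p <= 0)) {
    stop("nonpositive prevalence: log undefined", call. = FALSE)
  }
  d <- direct_prev
  d$log_p <- log(d$p)
  for (nm in c("age", "sex", "region", "urban", "year")) {
    if (!nm %in% names(d)) {
      stop("`direct_prev` lacks column `", nm, "`", call. = FALSE)
    }
    d[[nm]] <- factor(d[[nm]])
  }
  # same main effects and interactions as the system model; the age main
  # effect absorbs the age-specific bias term, year enters as a factor.
  # dimensions that are constant in the data (singleton grids) drop out.
  nlev <- vapply(d[c("age", "sex", "region", "urban", "year")], nlevels, 1L)
  keep <- names(nlev)[nlev >= 2]
  mains <- keep
  inters <- intersect(c("age:sex", "age:year", "sex:year"),
                      vapply(list(c("age", "sex"), c("age", "year"),
                                  c("sex", "year")),
                             function(pr) if (all(pr %in% keep))
                               paste(pr, collapse = ":") else "", ""))
  rhs <- paste(c(mains, inters, "1"), collapse = " + ")
  form <- stats::as.formula(paste("log_p ~", rhs))
  fit <- stats::lm(form, data = d)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    stop("design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  df_res <- fit$df.residual
  if (df_res < 1) {
    stop("no residual degrees of freedom: design is saturated",
         call. = FALSE)
  }
  list(
    sigma2_hat = sum(stats::residuals(fit)^2) / df_res,
    residuals = stats::residuals(fit),
    df_residual = df_res,
    fit = fit
  )
}

#' @rdname fit_bias_regression
#' @param df Degrees of freedom of the scaled inverse-chi-squared prior
#'   (default 30).
#' @param scale2 Scale-squared parameter; defaults to the regression
#'   estimate rounded to 3 decimals.
#' @return `calibrate_admin_prior()` returns a list with the
#'   [prior_scaled_inv_chisq()] `prior`, the raw `sigma2_hat`, and the
#'   implied central 95% `interval`.
#' @export
calibrate_admin_prior <- function(direct_prev, df = 30, scale2 = NULL) {
  reg <- fit_bias_regression(direct_prev)
  if (is.null(scale2)) scale2 <- round(reg$sigma2_hat, 3)
  prior <- prior_scaled_inv_chisq(df = df, scale2 = scale2)
  list(prior = prior, sigma2_hat = reg$sigma2_hat,
       interval = central_interval(prior, 0.95), regression = reg)
}
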