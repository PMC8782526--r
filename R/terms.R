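#' Term structures for the logit-linear predictor
#'
#' The linear predictor on the logit scale is a sum of term-structured
#' effects: an intercept, main effects for each grid dimension, and
#' interactions. Each term carries exactly one prior family. The standard
#' structure for the within-country model is an intercept (normal, sd 10),
#' age and sex main effects and an age-sex interaction (normal, sd 1),
#' exchangeable region and urban main effects (hierarchical normal with
#' half-normal sd), and damped-linear-trend priors on the year main effect
#' and the age-year and sex-year interactions. Trend variance and damping
#' hyperparameters are shared across the chains of an interaction (each age
#' has its own level/drift states, but one set of taus and phi).
#'
#' @param name Term name; dimensions joined by `:` (e.g. `"age:year"`),
#'   or `"(Intercept)"`.
#' @param dims Character vector of grid dimensions the term varies over
#'   (empty for the intercept).
#' @param prior A prior family object from [priors].
#' @return `term_spec()` returns a one-row tibble; `term_structure()` binds
#'   term specs into a `prev_terms` tibble after validity checks.
#' @examples
#' term_structure(
#'   term_spec("(Intercept)", character(), prior_normal(0, 10)),
#'   term_spec("age", "age", prior_normal(0, 1))
#' )
#' @export
term_spec <- function(name, dims, prior) {
  stopifnot(is.character(name), length(name) == 1, inherits(prior, "prev_prior"))
  dims <- as.character(dims)
  if (anyDuplicated(dims) > 0) stop("duplicate dimensions in term", call. = FALSE)
  tibble::tibble(term = name, dims = list(dims), prior = list(prior))
}

#' @rdname term_spec
#' @param ... One-row tibbles from `term_spec()`.
#' @export
term_structure <- function(...) {
  out <- dplyr::bind_rows(...)
  if (anyDuplicated(out$term) > 0) {
    stop("duplicate term names", call. = FALSE)
  }
  key <- vapply(out$dims, function(d) paste(sort(d), collapse = ":"), "")
  if (anyDuplicated(key) > 0) {
    stop("two terms cover the same dimension subset", call. = FALSE)
  }
  class(out) <- c("prev_terms", class(out))
  out
}

#' Default term structures
#'
#' `default_terms()` builds the standard term structure for a
#' within-country grid; `panel_terms()` the structure for the international
#' panel model (intercept, country, sex, country-sex, year). Time terms
#' take their hyperpriors from `time_prior`, `age_time_prior` and
#' `sex_time_prior`, so informative extracted hyperpriors can be dropped
#' in via [hyperpriors_to_trend_prior()].
#'
#' @param grid A [prev_grid()] or [panel_grid()].
#' @param time_prior,age_time_prior,sex_time_prior [prior_damped_trend()]
#'   objects for the year main effect and the two time interactions.
#' @return A `prev_terms` tibble.
#' @export
default_terms <- function(grid,
                          time_prior = prior_damped_trend(),
                          age_time_prior = time_prior,
                          sex_time_prior = time_prior) {
  stopifnot(inherits(grid, "prev_grid"))
  term_structure(
    term_spec("(Intercept)", character(), prior_normal(0, 10)),
    term_spec("age", "age", prior_normal(0, 1)),
    term_spec("sex", "sex", prior_normal(0, 1)),
    term_spec("region", "region", prior_hier_normal()),
    term_spec("urban", "urban", prior_hier_normal()),
    term_spec("year", "year", time_prior),
    term_spec("age:sex", c("age", "sex"), prior_normal(0, 1)),
    term_spec("age:year", c("age", "year"), age_time_prior),
    term_spec("sex:year", c("sex", "year"), sex_time_prior)
  )
}

#' @rdname default_terms
#' @export
panel_terms <- function(grid, time_prior = prior_damped_trend()) {
  stopifnot(inherits(grid, "prev_grid"))
  term_structure(
    term_spec("(Intercept)", character(), prior_normal(0, 10)),
    term_spec("country", "country", prior_hier_normal()),
    term_spec("sex", "sex", prior_normal(0, 1)),
    term_spec("country:sex", c("country", "sex"), prior_hier_normal()),
    term_spec("year", "year", time_prior)
  )
}

#' Cell-to-level design assignment
#'
#' For every grid cell and every term, computes the index of the term level
#' that contributes to that cell — the sparse equivalent of a 0/1 design
#' matrix with exactly one 1 per (cell, term). Terms whose dimensions
#' include the time dimension are laid out with non-time levels varying
#' fastest, so each non-time combination forms one trend chain over years.
#'
#' @param terms A `prev_terms` structure.
#' @param grid The grid the terms apply to.
#' @return A list of class `prev_design`: per term, a list with `idx`
#'   (integer vector over cells), `n_levels`, `labels`, `dims`, and for
#'   time-bearing terms `n_chain` (non-time combinations) and `n_time`.
#' @export
build_design <- function(terms, grid) {
  stopifnot(inherits(terms, "prev_terms"), inherits(grid, "prev_grid"))
  tdim <- grid$time_dim
  out <- purrr::pmap(list(terms$term, terms$dims, terms$prior),
                     function(nm, dims, prior) {
    bad <- setdiff(dims, names(grid$dims))
    if (length(bad)) {
      stop("term `", nm, "` uses dimension(s) absent from the grid: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # canonical order: non-time dims in grid order, then time
    dims <- c(intersect(names(grid$dims), setdiff(dims, tdim)),
              intersect(dims, tdim))
    if (length(dims) == 0) {
      return(list(idx = rep(1L, grid$n_cells), n_levels = 1L,
                  labels = "(Intercept)", dims = dims, prior = prior))
    }
    lens <- lengths(grid$dims)[dims]
    idx <- rep(1L, grid$n_cells)
    mult <- 1L
    for (d in dims) {
      idx <- idx + (cell_dim_index(grid, d) - 1L) * mult
      mult <- mult * lens[[d]]
    }
    labs <- do.call(paste, c(expand.grid(
      lapply(grid$dims[dims], as.character),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    ), sep = "."))
    res <- list(idx = idx, n_levels = as.integer(prod(lens)), labels = labs,
                dims = dims, prior = prior)
    if (tdim %in% dims) {
      res$n_time <- lens[[tdim]]
      res$n_chain <- as.integer(prod(lens) / lens[[tdim]])
    }
    res
  })
  names(out) <- terms$term
  structure(out, class = "prev_design", grid = grid)
}

#' Evaluate the logit-scale linear predictor
#'
#' Sums, for each grid cell, the effect values assigned by the design: the
#' sparse matrix-vector product of the 0/1 design with the stacked effect
#' vector.
#'
#' @param effects Named list: one numeric vector per term, of length
#'   `n_levels`.
#' @param design A `prev_design` from [build_design()].
#' @return Numeric vector of logit-prevalence means, one per cell.
#' @export
linear_predictor <- function(effects, design) {
  stopifnot(inherits(design, "prev_design"))
  if (!setequal(names(effects), names(design))) {
    stop("effect names do not match design terms", call. = FALSE)
  }
  mu <- 0
  for (nm in names(design)) {
    b <- effects[[nm]]
    if (length(b) != design[[nm]]$n_levels) {
      stop("effect `", nm, "` has length ", length(b), ", expected ",
           design[[nm]]$n_levels, call. = FALSE)
    }
    mu <- mu + b[design[[nm]]$idx]
  }
  mu
}
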