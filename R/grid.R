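#' Classification grids
#'
#' A classification grid defines the index sets over which prevalence is
#' modelled: demographic dimensions (age, sex, and optionally region and
#' urban-rural residence) crossed with a contiguous run of calendar years.
#' The year axis is split into an observed span (years for which data may
#' exist) and a forecast horizon; both are modelled identically, so
#' interpolation of past gaps and forecasting of future years use the same
#' machinery.
#'
#' `prev_grid()` builds the grid for the within-country prevalence model;
#' `panel_grid()` builds the country-by-sex-by-year grid used for the
#' international panel model from which trend hyperpriors are extracted.
#' Dimensions may be singletons (e.g. one region), so national and
#' subnational models share one code path.
#'
#' @param ages,sexes,regions,urban Character vectors of ordered,
#'   duplicate-free labels. `regions` and `urban` default to singletons for
#'   national models.
#' @param years Integer vector of contiguous calendar years (step 1).
#' @param data_until Last year of the observed span; later years form the
#'   forecast horizon. Defaults to the last year (no forecast).
#' @param countries Character vector of country labels for `panel_grid()`.
#' @return An object of class `prev_grid`: a list with `dims` (named list of
#'   label vectors, time dimension last), `time_dim`, `data_until`, and
#'   `n_cells`.
#' @examples
#' g <- prev_grid(
#'   ages = c("2-4", "5-9"), sexes = c("F", "M"),
#'   years = 2000:2010, data_until = 2008
#' )
#' g$n_cells
#' @export
prev_grid <- function(ages, sexes, regions = "all", urban = "all",
                      years, data_until = max(years)) {
  dims <- list(
    age = as.character(ages), sex = as.character(sexes),
    region = as.character(regions), urban = as.character(urban),
    year = years
  )
  new_grid(dims, data_until)
}

#' @rdname prev_grid
#' @export
panel_grid <- function(countries, sexes, years, data_until = max(years)) {
  dims <- list(
    country = as.character(countries), sex = as.character(sexes),
    year = years
  )
  new_grid(dims, data_until)
}

new_grid <- function(dims, data_until) {
  stopifnot(names(dims)[length(dims)] == "year")
  years <- dims$year
  if (!is.numeric(years) || length(years) < 1 ||
      (length(years) > 1 && any(diff(years) != 1))) {
    stop("`years` must be contiguous integers with step 1", call. = FALSE)
  }
  years <- as.integer(years)
  dims$year <- years
  for (nm in setdiff(names(dims), "year")) {
    v <- dims[[nm]]
    if (length(v) < 1 || anyDuplicated(v) > 0 || any(is.na(v)) || any(v == "")) {
      stop("dimension `", nm, "` must be non-empty and duplicate-free",
           call. = FALSE)
    }
  }
  if (!data_until %in% years) {
    stop("`data_until` must be one of `years`", call. = FALSE)
  }
  structure(
    list(
      dims = dims,
      time_dim = "year",
      data_until = as.integer(data_until),
      n_cells = prod(lengths(dims))
    ),
    class = "prev_grid"
  )
}

#' @export
print.prev_grid <- function(x, ...) {
  cat("<prev_grid> ", x$n_cells, " cells\n", sep = "")
  for (nm in names(x$dims)) {
    v <- x$dims[[nm]]
    cat("  ", nm, " (", length(v), "): ", paste(utils::head(v, 6), collapse = ", "),
        if (length(v) > 6) ", ..." else "", "\n", sep = "")
  }
  cat("  observed span to ", x$data_until, ", forecast horizon ",
      forecast_horizon(x), " year(s)\n", sep = "")
  invisible(x)
}

#' @rdname prev_grid
#' @export
forecast_horizon <- function(grid) {
  sum(grid$dims$year > grid$data_until)
}

#' Enumerate the cells of a classification grid
#'
#' Returns one row per cell in the grid's canonical order (first dimension
#' varies fastest, year slowest), with a `cell` integer index and a
#' `forecast` flag for cells beyond the observed span.
#'
#' @param grid A [prev_grid()].
#' @return A tibble with one column per grid dimension plus `cell` and
#'   `forecast`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "prev_grid"))
  df <- expand.grid(grid$dims,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  out$cell <- seq_len(nrow(out))
  out$forecast <- out$year > grid$data_until
  out
}

# integer index (1-based) of each cell along dimension `dim`
cell_dim_index <- function(grid, dim) {
  lens <- lengths(grid$dims)
  k <- match(dim, names(grid$dims))
  if (is.na(k)) stop("unknown grid dimension `", dim, "`", call. = FALSE)
  inner <- if (k == 1) 1L else prod(lens[seq_len(k - 1)])
  rep(rep(seq_len(lens[k]), each = inner), length.out = grid$n_cells)
}

# map a data frame of dimension labels to cell indices; errors name the
# offending row/column. `df` must contain all grid dimensions.
cells_from_labels <- function(grid, df) {
  lens <- lengths(grid$dims)
  idx <- rep(1L, nrow(df))
  mult <- 1L
  for (nm in names(grid$dims)) {
    if (!nm %in% names(df)) {
      stop("missing column `", nm, "`", call. = FALSE)
    }
    m <- match(df[[nm]], grid$dims[[nm]])
    if (anyNA(m)) {
      bad <- which(is.na(m))[1]
      stop("unknown label `", df[[nm]][bad], "` in column `", nm,
           "` (row ", bad, ")", call. = FALSE)
    }
    idx <- idx + (m - 1L) * mult
    mult <- mult * lens[[nm]]
  }
  idx
}
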