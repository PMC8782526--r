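test_that("design assignment counts parameters and contributions", {
  g <- prev_grid(ages = c("a1", "a2"), sexes = c("F", "M"),
                 years = 2000:2002)
  terms <- term_structure(
    term_spec("(Intercept)", character(), prior_normal(0, 10)),
    term_spec("age", "age", prior_normal()),
    term_spec("sex", "sex", prior_normal()),
    term_spec("year", "year", prior_normal()),
    term_spec("age:sex", c("age", "sex"), prior_normal()),
    term_spec("age:year", c("age", "year"), prior_normal()),
    term_spec("sex:year", c("sex", "year"), prior_normal())
  )
  d <- build_design(terms, g)
  # total parameter count 1+2+2+3+4+6+6 = 24
  expect_equal(sum(vapply(d, function(x) x$n_levels, 1L)), 24L)
  # every cell receives exactly one level of every term
  for (tm in d) {
    expect_length(tm$idx, 12)
    expect_true(all(tm$idx >= 1 & tm$idx <= tm$n_levels))
  }
})

test_that("singleton dimensions add length-one terms", {
  g <- prev_grid(ages = c("a1", "a2"), sexes = c("F", "M"),
                 years = 2000:2002)
  terms <- default_terms(g)
  d <- build_design(terms, g)
  expect_equal(d$region$n_levels, 1L)
  expect_equal(d$urban$n_levels, 1L)
  expect_true(all(d$region$idx == 1L))
})

test_that("terms referencing unknown dimensions fail", {
  g <- tiny_grid()
  terms <- term_structure(
    term_spec("province", "province", prior_normal())
  )
  expect_error(build_design(terms, g), "province")
  expect_error(term_structure(term_spec("a", "age", prior_normal()),
                              term_spec("a2", "age", prior_normal())),
               "same dimension subset")
})

test_that("linear predictor equals the dense design product", {
  g <- prev_grid(ages = c("a1", "a2", "a3"), sexes = c("F", "M"),
                 years = 2000:2004)
  terms <- default_terms(g)
  d <- build_design(terms, g)
  set.seed(4)
  effects <- lapply(d, function(tm) rnorm(tm$n_levels))
  mu <- linear_predictor(effects, d)
  # dense 0/1 design oracle
  X <- do.call(cbind, lapply(d, function(tm) {
    m <- matrix(0, g$n_cells, tm$n_levels)
    m[cbind(seq_len(g$n_cells), tm$idx)] <- 1
    m
  }))
  expect_equal(mu, as.vector(X %*% unlist(effects)), tolerance = 1e-12)
  # all-zero effects give logit 0 -> prevalence one half
  mu0 <- linear_predictor(lapply(d, function(tm) numeric(tm$n_levels)), d)
  expect_equal(unique(mu0), 0)
  # intercept -2 alone
  eff <- lapply(d, function(tm) numeric(tm$n_levels))
  eff[["(Intercept)"]] <- -2
  expect_equal(unique(1 / (1 + exp(-linear_predictor(eff, d)))),
               1 / (1 + exp(2)))
})

test_that("time-bearing terms are laid out chain-fastest", {
  g <- prev_grid(ages = c("a1", "a2"), sexes = "F", years = 2000:2002)
  d <- build_design(default_terms(g), g)
  ay <- d[["age:year"]]
  expect_equal(ay$n_chain, 2L)
  expect_equal(ay$n_time, 3L)
  expect_equal(ay$labels[1:3], c("a1.2000", "a2.2000", "a1.2001"))
})
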