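# Cell probabilities, linear predictors, parameter counts and constraint
# validation of the proportional-odds model family.

test_that("equal-probability cutpoints give uniform cell probabilities", {
  expect_equal(po_probs(c(log(1/2), log(2)), 0), rep(1/3, 3),
               tolerance = 1e-12)
  expect_equal(po_probs(c(log(1/4), log(2/3), log(3/2), log(4)), 0),
               rep(0.2, 5), tolerance = 1e-12)
  expect_equal(po_probs(0, 0), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("cell probabilities normalise and cumulate to the logistic CDF", {
  set.seed(41)
  for (rep in 1:200) {
    q <- sample(2:7, 1)
    mu <- sort(rnorm(q - 1, sd = 2))
    if (any(diff(mu) <= 0)) next
    eta <- rnorm(1, sd = 3)
    th <- po_probs(mu, eta)
    expect_length(th, q)
    expect_true(all(th >= 0))
    expect_equal(sum(th), 1, tolerance = 1e-12)
    expect_equal(cumsum(th)[seq_len(q - 1)], plogis(mu - eta),
                 tolerance = 1e-10)
  }
})

test_that("increasing eta strictly lowers every cumulative probability", {
  set.seed(42)
  for (rep in 1:100) {
    q <- sample(3:6, 1)
    mu <- sort(rnorm(q - 1, sd = 2))
    if (any(diff(mu) <= 0)) next
    eta <- rnorm(1)
    delta <- runif(1, 0.1, 2)
    lo <- cumsum(po_probs(mu, eta))[seq_len(q - 1)]
    hi <- cumsum(po_probs(mu, eta + delta))[seq_len(q - 1)]
    expect_true(all(hi < lo))
  }
})

test_that("degenerate cutpoints and q < 2 are rejected", {
  expect_error(po_probs(c(1, 0), 0), "increasing")
  expect_error(po_probs(numeric(0), 0), "q >= 2")
  expect_error(po_probs(0, Inf), "finite")
})

test_that("linear predictor adds the requested effects", {
  null_spec <- pofm_spec("single", "single")
  expect_identical(linear_predictor(pofm_params(mu = 0), null_spec, 1, 1), 0)

  spec <- pofm_spec("clustered", "clustered", R = 2, C = 2)
  par <- pofm_params(mu = c(-1, 1), alpha = c(0, 1), beta = c(0, -1),
                     pi = c(.5, .5), kappa = c(.5, .5))
  expect_identical(linear_predictor(par, spec, 2, 2), 0)

  ispec <- pofm_spec("clustered", "clustered", R = 2, C = 2,
                     interaction = TRUE)
  ipar <- pofm_params(mu = c(-1, 1), alpha = c(0, 1), beta = c(0, -1),
                      gamma = matrix(c(.5, -.5, -.5, .5), 2), pi = c(.5, .5),
                      kappa = c(.5, .5))
  expect_identical(linear_predictor(ipar, ispec, 2, 2), 0.5)
  expect_error(linear_predictor(par, ispec, 2, 2), "gamma")
  expect_error(linear_predictor(par, spec, 3, 1), "out of range")
})

test_that("parameter counts match the model-family arithmetic", {
  expect_identical(
    pofm_nparams(pofm_spec("clustered", "clustered", R = 3, C = 2),
                 99, 100, q = 4), 9L)
  expect_identical(
    pofm_nparams(pofm_spec("clustered", "clustered", R = 3, C = 2,
                           interaction = TRUE), 12, 16, q = 6), 13L)
  expect_identical(
    pofm_nparams(pofm_spec("saturated", "saturated"), 12, 16, q = 6), 31L)
  expect_identical(pofm_nparams(pofm_spec("single", "single"), 10, 5, 4), 3L)
})

test_that("parameter counts agree with counting free values in the container", {
  # brute force: count the free entries a parameter container would hold
  free_count <- function(spec, n, p, q) {
    g <- pofm:::spec_groups(spec, n, p)
    cnt <- (q - 1) +                       # cutpoints
      (g$GR - 1) +                         # row effects above the baseline
      (g$GC - 1)                           # column effects above the baseline
    if (spec$interaction) cnt <- cnt + (g$GR - 1) * (g$GC - 1)
    if (spec$rows == "clustered") cnt <- cnt + spec$R - 1
    if (spec$cols == "clustered") cnt <- cnt + spec$C - 1
    cnt
  }
  n <- 8; p <- 6; q <- 3
  specs <- list(
    pofm_spec("clustered", "single", R = 2),
    pofm_spec("clustered", "saturated", R = 2),
    pofm_spec("clustered", "saturated", R = 2, interaction = TRUE),
    pofm_spec("single", "clustered", C = 3),
    pofm_spec("saturated", "clustered", C = 3),
    pofm_spec("saturated", "clustered", C = 3, interaction = TRUE),
    pofm_spec("clustered", "clustered", R = 2, C = 3),
    pofm_spec("clustered", "clustered", R = 2, C = 3, interaction = TRUE))
  # expected counts from the family's closed formulas
  expected <- c((q-1) + 2*2 - 2,
                (q-1) + 2*2 + p - 3,
                (q-1) + 2*p + 2 - 2,
                (q-1) + 2*3 - 2,
                (q-1) + 2*3 + n - 3,
                (q-1) + 3*n + 3 - 2,
                (q-1) + 2*2 + 2*3 - 4,
                (q-1) + 2*3 + 2 + 3 - 3)
  for (i in seq_along(specs)) {
    expect_identical(pofm_nparams(specs[[i]], n, p, q), as.integer(expected[i]))
    expect_identical(pofm_nparams(specs[[i]], n, p, q),
                     as.integer(free_count(specs[[i]], n, p, q)))
  }
})

test_that("constraint validation reports each violated constraint", {
  spec <- pofm_spec("clustered", "clustered", R = 2, C = 2)
  good <- pofm_params(mu = c(-1, 0, 1), alpha = c(0, 1), beta = c(0, -1),
                      pi = c(.4, .6), kappa = c(.5, .5))
  expect_length(validate_params(good, spec), 0)

  expect_match(validate_params(pofm_params(mu = c(1, 0))),
               "increasing", all = FALSE)
  bad_pi <- pofm_params(mu = 0, alpha = c(0, 1), pi = c(0.6, 0.6))
  expect_match(validate_params(bad_pi), "sum", all = FALSE)
  bad_gamma <- pofm_params(mu = 0, alpha = c(0, 1), beta = c(0, 1),
                           gamma = matrix(1, 2, 2))
  expect_match(validate_params(bad_gamma), "gamma", all = FALSE)
  # spec-aware checks: missing components are named
  expect_match(validate_params(pofm_params(mu = 0), spec), "pi", all = FALSE)
})

test_that("ordinal matrices enforce declared q and round-trip through CSV", {
  expect_error(ordinal_matrix(matrix(c(1, 4), 1, 2), q = 3), "1..q")
  expect_error(ordinal_matrix(matrix(1, 2, 2), q = 1), "q")
  y <- ordinal_matrix(matrix(sample.int(3, 12, TRUE), 3, 4), q = 5)
  expect_identical(attr(y, "q"), 5L)   # declared, not inferred

  path <- withr::local_tempfile(fileext = ".csv")
  write_ordinal_csv(y, path)
  back <- read_ordinal_csv(path, q = 5)
  expect_equal(unclass(back)[, ], unclass(y)[, ], ignore_attr = TRUE)

  # zero-based convenience shift
  writeLines("0,1\n2,0", path)
  z <- read_ordinal_csv(path, q = 3, zero_based = TRUE)
  expect_equal(as.integer(z), c(1L, 3L, 2L, 1L))
})
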