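# EM steps and the full fitting loop: exactness of the E-step, M-step
# optimality against an independent optimiser, ascent, determinism, and the
# reversal symmetry of the cumulative-logit parameterisation.

test_that("one-component posteriors are degenerate", {
  inst <- random_instance(n = 5, p = 3, q = 3, R = 1, C = 1, seed = 4)
  spec <- pofm_spec("clustered", "single", R = 1)
  par <- pofm_params(mu = inst$mu, alpha = 0, pi = 1)
  post <- e_step(inst$data, par, spec)
  expect_equal(as.numeric(post$zhat), rep(1, 5))
})

test_that("one-mode posteriors equal Bayes' rule on a 1 x 2 matrix", {
  Y <- ordinal_matrix(matrix(c(1L, 2L), 1, 2), q = 2)
  mu <- 0.3; alpha <- c(0, 1.2); pi <- c(0.7, 0.3)
  spec <- pofm_spec("clustered", "single", R = 2)
  par <- pofm_params(mu = mu, alpha = alpha, pi = pi)
  post <- e_step(Y, par, spec)
  # two-term arithmetic: P(r | y) with independent cells
  lik <- sapply(1:2, function(r) {
    th <- oracle_theta(mu, alpha[r])
    pi[r] * th[1] * th[2]
  })
  expect_equal(as.numeric(post$zhat), lik / sum(lik), tolerance = 1e-12)
})

test_that("widely separated blocks give near-hard posteriors", {
  cfg <- pofm_sim_config(n = 40, p = 50, q = 3, alpha = c(0, 8))
  sim <- pofm_simulate(cfg, seed = 5)
  spec <- pofm_spec("clustered", "single", R = 2)
  par <- pofm_params(mu = cfg$params$mu, alpha = c(0, 8), pi = c(.5, .5))
  post <- e_step(sim$data, par, spec)
  expect_true(all(pmin(post$zhat, 1 - post$zhat) < 1e-3))
})

test_that("null-model M-step reproduces empirical cumulative logits", {
  set.seed(9)
  Y <- ordinal_matrix(matrix(sample.int(4, 200, TRUE,
                                        prob = c(.1, .3, .4, .2)), 20, 10),
                      q = 4)
  spec <- pofm_spec("single", "single")
  start <- pofm_params(mu = c(-1, 0, 1))
  fitted <- m_step(Y, spec, list(zhat = NULL, xhat = NULL), start)
  emp <- qlogis(cumsum(tabulate(as.integer(Y), 4))[1:3] / 200)
  expect_equal(fitted$mu, emp, tolerance = 1e-6)
  # the closed-form path of the full fit agrees
  expect_equal(pofm_fit(Y, spec)$params$mu, emp, tolerance = 1e-8)
})

test_that("mixing-proportion updates are posterior column means", {
  inst <- random_instance(n = 6, p = 4, q = 3, R = 2, C = 1, seed = 23)
  spec <- pofm_spec("clustered", "single", R = 2)
  par <- pofm_params(mu = inst$mu, alpha = inst$alpha, pi = inst$pi)
  post <- e_step(inst$data, par, spec)
  new <- m_step(inst$data, spec, post, par)
  expect_equal(new$pi, colMeans(post$zhat), tolerance = 1e-12)
})

test_that("M-step matches an independently optimised objective", {
  # same weighted complete-data objective coded from scratch and handed to
  # stats::optim as a cross-check of the Newton maximiser
  inst <- random_instance(n = 12, p = 6, q = 3, R = 2, C = 2, seed = 77)
  spec <- pofm_spec("clustered", "clustered", R = 2, C = 2)
  set.seed(1)
  post <- list(zhat = t(apply(matrix(rgamma(24, 2), 12), 1,
                              function(x) x / sum(x))),
               xhat = t(apply(matrix(rgamma(12, 2), 6), 1,
                              function(x) x / sum(x))))
  start <- pofm_params(mu = inst$mu, alpha = c(0, 0), beta = c(0, 0),
                       pi = c(.5, .5), kappa = c(.5, .5))
  fitted <- m_step(inst$data, spec, post, start)

  W <- pofm:::cpp_weight_cube(pofm:::unclass_matrix(inst$data), 3,
                              post$zhat, post$xhat)
  ref_obj <- function(x) {
    mu <- c(x[1], x[1] + exp(x[2]))
    alpha <- c(0, x[3]); beta <- c(0, x[4])
    val <- 0
    for (r in 1:2) for (cc in 1:2) {
      th <- oracle_theta(mu, alpha[r] + beta[cc])
      val <- val + sum(W[r, cc, ] * log(th))
    }
    -val
  }
  ref <- optim(c(inst$mu[1], log(diff(inst$mu)), 0, 0), ref_obj,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  attained <- pofm:::cpp_weighted_loglik(W, fitted$mu, fitted$alpha,
                                         fitted$beta, matrix(0, 2, 2))
  expect_gte(attained, -ref$value - 1e-4)
  expect_equal(attained, -ref$value, tolerance = 1e-4)
})

test_that("the EM objective never decreases within a run", {
  for (s in 1:10) {
    n <- 30; p <- 8
    cfg <- pofm_sim_config(n = n, p = p, q = 3, alpha = c(0, 1, 2),
                           beta = c(0, -1))
    sim <- pofm_simulate(cfg, seed = 400 + s)
    spec <- if (s %% 2 == 0) pofm_spec("clustered", "single", R = 2)
            else pofm_spec("clustered", "clustered", R = 2, C = 2)
    fit <- pofm_fit(sim$data, spec, n_starts = 2, seed = s)
    expect_true(all(diff(fit$trace) >= -1e-8))
    expect_gte(fit$entropy, -1e-8)
    expect_lte(fit$loglik_complete, fit$loglik + 1e-8)
  }
})

test_that("reported likelihood matches the likelihood operation", {
  cfg <- pofm_sim_config(n = 20, p = 6, q = 3, alpha = c(0, 2),
                         beta = c(0, -1))
  sim <- pofm_simulate(cfg, seed = 2)
  spec <- pofm_spec("clustered", "clustered", R = 2, C = 2)
  fit <- pofm_fit(sim$data, spec, n_starts = 4, seed = 3)
  expect_identical(fit$loglik_flag, "exact")
  redo <- loglik_bicluster(sim$data, fit$params, spec, method = "exact")
  expect_equal(fit$loglik, redo$loglik, tolerance = 1e-8)

  one <- pofm_fit(sim$data, pofm_spec("clustered", "single", R = 2),
                  n_starts = 4, seed = 3)
  expect_equal(one$loglik,
               loglik_row_mixture(sim$data, one$params, one$spec),
               tolerance = 1e-8)
})

test_that("refitting with the same seed reproduces the result bitwise", {
  cfg <- pofm_sim_config(n = 25, p = 8, q = 3, alpha = c(0, 1.5),
                         beta = c(0, -1))
  sim <- pofm_simulate(cfg, seed = 10)
  spec <- pofm_spec("clustered", "clustered", R = 2, C = 2)
  f1 <- pofm_fit(sim$data, spec, n_starts = 5, seed = 99)
  f2 <- pofm_fit(sim$data, spec, n_starts = 5, seed = 99)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$posteriors$zhat, f2$posteriors$zhat)
})

test_that("reversing the category order is a likelihood-preserving symmetry", {
  # deterministic identity: theta_k(mu, eta) = theta_{q+1-k}(-rev(mu), -eta)
  inst <- random_instance(n = 5, p = 4, q = 4, R = 2, C = 1, seed = 66)
  spec <- pofm_spec("clustered", "single", R = 2)
  par <- pofm_params(mu = inst$mu, alpha = inst$alpha, pi = inst$pi)
  q <- 4
  rev_data <- ordinal_matrix(q + 1L - unclass(inst$data)[, ], q)
  rev_par <- pofm_params(mu = -rev(inst$mu), alpha = -inst$alpha,
                         pi = inst$pi)
  expect_equal(loglik_row_mixture(inst$data, par, spec),
               loglik_row_mixture(rev_data, rev_par, spec),
               tolerance = 1e-10)

  # and at the level of the maximised likelihood
  cfg <- pofm_sim_config(n = 30, p = 10, q = 4, alpha = c(0, 2))
  sim <- pofm_simulate(cfg, seed = 21)
  fit_fwd <- pofm_fit(sim$data, spec, n_starts = 6, seed = 5)
  fit_rev <- pofm_fit(ordinal_matrix(q + 1L - unclass(sim$data)[, ], q),
                      spec, n_starts = 6, seed = 5)
  expect_equal(fit_fwd$loglik, fit_rev$loglik, tolerance = 1e-5)
})

test_that("saturated-mode models fit deterministically without a mixture", {
  inst <- random_instance(n = 6, p = 5, q = 3, R = 1, C = 1, seed = 30)
  spec <- pofm_spec("saturated", "single")
  fit <- pofm_fit(inst$data, spec)
  expect_identical(fit$entropy, 0)
  expect_length(fit$params$alpha, 6)
  expect_identical(fit$params$alpha[1], 0)
  expect_identical(fit$nu, (3L - 1L) + (6L - 1L))
})
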