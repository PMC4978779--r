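# Likelihood machinery shared by the EM fitter and the model-selection
# criteria.  All mixture sums are evaluated in log space (log-sum-exp).

# membership matrix of a fixed (non-clustered) mode, or the posteriors of a
# clustered one
membership_matrix <- function(structure, size, posteriors = NULL) {
  switch(structure,
    single    = matrix(1, size, 1L),
    saturated = diag(size),
    clustered = {
      if (is.null(posteriors))
        stop("clustered mode needs posterior memberships", call. = FALSE)
      as.matrix(posteriors)
    })
}

log_mix <- function(w) log(pmax(w, 1e-10))

entropy_of <- function(post) {
  if (is.null(post)) return(0)
  -sum(post * log(pmax(post, 1e-300)))
}

coerce_data <- function(data, q = NULL) {
  if (inherits(data, "ordinal_matrix")) return(data)
  if (is.null(q))
    stop("supply an ordinal_matrix(), or a plain matrix together with q",
         call. = FALSE)
  ordinal_matrix(data, q)
}

# number of column-assignment terms is C^p; exact enumeration is only
# attempted when that count stays within 2^20
exact_feasible <- function(C, p) p * log(C) <= 20 * log(2) + 1e-9

#' Incomplete-data log-likelihood of a row-mixture model
#'
#' Exact marginal log-likelihood when only the rows are clustered (columns
#' `"single"` or `"saturated"`):
#' `sum_i log sum_r pi_r prod_j theta[r, c(j), y_ij]`, evaluated with
#' log-sum-exp over the row components.
#'
#' @param data an [ordinal_matrix()].
#' @param params a [pofm_params()] with `pi` present.
#' @param spec a [pofm_spec()] with clustered rows and non-clustered columns.
#' @return scalar log-likelihood.
#' @export
loglik_row_mixture <- function(data, params, spec) {
  data <- coerce_data(data)
  if (spec$rows != "clustered" || spec$cols == "clustered")
    stop("loglik_row_mixture needs clustered rows and non-clustered columns",
         call. = FALSE)
  X <- membership_matrix(spec$cols, ncol(data))
  res <- cpp_estep_rows(unclass_matrix(data), attr(data, "q"), X,
                        logtheta_array(params), log_mix(params$pi))
  res$loglik
}

#' Incomplete-data log-likelihood of a column-mixture model
#'
#' Mirror image of [loglik_row_mixture()] for models where only the columns
#' are clustered.
#'
#' @inheritParams loglik_row_mixture
#' @export
loglik_col_mixture <- function(data, params, spec) {
  data <- coerce_data(data)
  if (spec$cols != "clustered" || spec$rows == "clustered")
    stop("loglik_col_mixture needs clustered columns and non-clustered rows",
         call. = FALSE)
  Z <- membership_matrix(spec$rows, nrow(data))
  res <- cpp_estep_cols(unclass_matrix(data), attr(data, "q"), Z,
                        logtheta_array(params), log_mix(params$kappa))
  res$loglik
}

#' Incomplete-data log-likelihood of a biclustering model
#'
#' With both modes clustered the marginal likelihood sums over every
#' assignment of the `p` columns to `C` clusters (the row mixture is
#' marginalised exactly within each term).  `method = "exact"` performs that
#' enumeration (allowed while `C^p <= 2^20`); `method = "bound"` returns the
#' mean-field variational lower bound
#' `F = loglik_complete + EN(zhat) + EN(xhat)` at the supplied posteriors;
#' `"auto"` picks the exact value when feasible.
#'
#' @inheritParams loglik_row_mixture
#' @param method `"auto"`, `"exact"` or `"bound"`.
#' @param posteriors posteriors list (`zhat`, `xhat`), required for the bound.
#' @return list with elements `loglik` and `method`
#'   (`"exact"` or `"variational_bound"`).
#' @export
loglik_bicluster <- function(data, params, spec,
                             method = c("auto", "exact", "bound"),
                             posteriors = NULL) {
  data <- coerce_data(data)
  method <- match.arg(method)
  if (spec$rows != "clustered" || spec$cols != "clustered")
    stop("loglik_bicluster needs both modes clustered", call. = FALSE)
  feasible <- exact_feasible(spec$C, ncol(data))
  if (method == "auto") method <- if (feasible) "exact" else "bound"
  if (method == "exact") {
    if (!feasible)
      stop("exact enumeration needs C^p <= 2^20; use method = 'bound'",
           call. = FALSE)
    GR <- length(params$alpha); GC <- length(params$beta)
    gamma <- if (is.null(params$gamma)) matrix(0, GR, GC) else params$gamma
    ll <- cpp_loglik_bicluster_exact(unclass_matrix(data), attr(data, "q"),
                                     params$mu, params$alpha, params$beta,
                                     gamma, log_mix(params$pi),
                                     log_mix(params$kappa))
    return(list(loglik = ll, method = "exact"))
  }
  if (is.null(posteriors))
    stop("the variational bound is evaluated at given posteriors", call. = FALSE)
  lc <- loglik_complete(data, params, spec, posteriors)
  list(loglik = lc + entropy_of(posteriors$zhat) + entropy_of(posteriors$xhat),
       method = "variational_bound")
}

#' Expected complete-data log-likelihood
#'
#' `sum_ir zhat log pi + sum_jc xhat log kappa +
#'  sum_ijrc zhat_ir xhat_jc log theta[r, c, y_ij]`, with the terms of
#' non-clustered modes dropped and the joint membership expectation
#' factorised as `zhat_ir xhat_jc` (mean-field approximation).
#'
#' @inheritParams loglik_row_mixture
#' @param posteriors list with `zhat` and/or `xhat` for the clustered modes.
#' @return scalar expected complete-data log-likelihood.
#' @export
loglik_complete <- function(data, params, spec, posteriors = NULL) {
  data <- coerce_data(data)
  n <- nrow(data); p <- ncol(data)
  Z <- membership_matrix(spec$rows, n, posteriors$zhat)
  X <- membership_matrix(spec$cols, p, posteriors$xhat)
  check_posterior_rows(Z)
  check_posterior_rows(X)
  W <- cpp_weight_cube(unclass_matrix(data), attr(data, "q"), Z, X)
  ll <- sum(W * logtheta_array(params))
  if (spec$rows == "clustered")
    ll <- ll + sum(Z %*% log_mix(params$pi))
  if (spec$cols == "clustered")
    ll <- ll + sum(X %*% log_mix(params$kappa))
  ll
}

check_posterior_rows <- function(M, tol = 1e-8) {
  if (any(abs(rowSums(M) - 1) > tol))
    stop("posterior membership rows must sum to 1", call. = FALSE)
  invisible(M)
}

unclass_matrix <- function(x) {
  attributes(x) <- attributes(x)[c("dim")]
  x
}

#' E-step: update posterior cluster memberships
#'
#' Row update: `zhat_ir` proportional to
#' `pi_r exp(sum_jc xhat_jc log theta[r, c, y_ij])`; the column update is the
#' mirror image.  For one-mode models this is the exact posterior (Bayes'
#' rule).  For two-mode models the two mean-field updates are alternated
#' until the largest membership change falls below `tol` or `max_cycles`
#' inner cycles have run.
#'
#' @inheritParams loglik_complete
#' @param max_cycles,tol inner alternation control for the two-mode case.
#' @return posteriors list (`zhat`, `xhat`; `NULL` for non-clustered modes)
#'   with attribute `"onemode_loglik"` carrying the exact incomplete-data
#'   log-likelihood when exactly one mode is clustered.
#' @export
e_step <- function(data, params, spec, posteriors = NULL,
                   max_cycles = 5L, tol = 1e-6) {
  data <- coerce_data(data)
  n <- nrow(data); p <- ncol(data); q <- attr(data, "q")
  Y <- unclass_matrix(data)
  L <- logtheta_array(params)
  rows_cl <- spec$rows == "clustered"
  cols_cl <- spec$cols == "clustered"
  out <- list(zhat = NULL, xhat = NULL)
  if (!rows_cl && !cols_cl) return(out)

  if (rows_cl && !cols_cl) {
    X <- membership_matrix(spec$cols, p)
    res <- cpp_estep_rows(Y, q, X, L, log_mix(params$pi))
    out$zhat <- res$post
    attr(out, "onemode_loglik") <- res$loglik
    return(out)
  }
  if (cols_cl && !rows_cl) {
    Z <- membership_matrix(spec$rows, n)
    res <- cpp_estep_cols(Y, q, Z, L, log_mix(params$kappa))
    out$xhat <- res$post
    attr(out, "onemode_loglik") <- res$loglik
    return(out)
  }

  # two-mode: alternate the coupled mean-field updates
  zhat <- if (!is.null(posteriors$zhat)) as.matrix(posteriors$zhat)
          else matrix(1 / spec$R, n, spec$R)
  xhat <- if (!is.null(posteriors$xhat)) as.matrix(posteriors$xhat)
          else matrix(1 / spec$C, p, spec$C)
  logpi <- log_mix(params$pi); logkappa <- log_mix(params$kappa)
  res <- cpp_estep_twomode(Y, q, zhat, xhat, L, logpi, logkappa,
                           as.integer(max_cycles), tol)
  out <- list(zhat = res$zhat, xhat = res$xhat)
  # The column update is coordinate-optimal given zhat, so the variational
  # bound collapses to the column normalisers plus the row prior and
  # entropy terms: F = sum_j xnorm_j + sum_ir zhat_ir log pi_r + EN(zhat).
  attr(out, "bound") <- res$xnorm + sum(res$zhat %*% logpi) +
    entropy_of(res$zhat)
  out
}

#' M-step: re-estimate parameters at fixed posteriors
#'
#' Mixing proportions have closed-form updates (posterior column means);
#' cutpoints, effects and interactions maximise the expected complete-data
#' log-likelihood by a Newton-type line search on an unconstrained
#' reparameterisation (cutpoints as first value plus log-increments, the
#' interaction through its free block).  The returned parameters never
#' decrease the expected complete-data log-likelihood relative to
#' `params_init`.
#'
#' @inheritParams loglik_complete
#' @param params_init warm-start parameters.
#' @return updated [pofm_params()] with attribute `"mstep_value"`, the
#'   attained weighted log-likelihood (prior terms excluded).
#' @export
m_step <- function(data, spec, posteriors, params_init) {
  data <- coerce_data(data)
  n <- nrow(data); p <- ncol(data); q <- attr(data, "q")
  Z <- membership_matrix(spec$rows, n, posteriors$zhat)
  X <- membership_matrix(spec$cols, p, posteriors$xhat)
  check_posterior_rows(Z)
  check_posterior_rows(X)
  W <- cpp_weight_cube(unclass_matrix(data), q, Z, X)
  g <- spec_groups(spec, n, p)
  gamma0 <- if (spec$interaction) {
    if (is.null(params_init$gamma)) matrix(0, g$GR, g$GC) else params_init$gamma
  } else matrix(0, g$GR, g$GC)
  # a partial maximisation (iteration cap) still ascends the objective,
  # which is all a generalised EM step requires
  res <- cpp_mstep_newton(W, q,
                          row_eff = g$GR > 1L, col_eff = g$GC > 1L,
                          inter = spec$interaction,
                          mu0 = params_init$mu,
                          alpha0 = params_init$alpha,
                          beta0 = params_init$beta, gamma0 = gamma0)
  out <- pofm_params(mu = as.numeric(res$mu),
                     alpha = as.numeric(res$alpha),
                     beta = as.numeric(res$beta),
                     gamma = if (spec$interaction) res$gamma,
                     pi = if (spec$rows == "clustered") colMeans(Z),
                     kappa = if (spec$cols == "clustered") colMeans(X))
  attr(out, "mstep_value") <- res$value
  out
}
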