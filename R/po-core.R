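#' Cell probabilities of the proportional-odds model
#'
#' For cutpoints `mu` and a linear-predictor offset `eta`, returns the `q`
#' category probabilities `theta[k] = F(mu[k] - eta) - F(mu[k-1] - eta)`
#' with `F` the standard logistic CDF (and `mu[0] = -Inf`, `mu[q] = +Inf`).
#' Increasing `eta` shifts mass towards higher categories: all cumulative
#' probabilities `P(Y <= k)` strictly decrease (the proportional-odds
#' property).
#'
#' @param mu strictly increasing vector of `q - 1` cutpoints.
#' @param eta finite scalar linear predictor.
#' @return probability vector of length `q` summing to 1.
#' @examples
#' po_probs(c(log(1/2), log(2)), 0)   # uniform over three categories
#' @export
po_probs <- function(mu, eta = 0) {
  mu <- as.numeric(mu)
  if (length(mu) < 1)
    stop("at least one cutpoint is required (q >= 2)", call. = FALSE)
  if (length(mu) > 1 && any(diff(mu) <= 0))
    stop("cutpoints must be strictly increasing", call. = FALSE)
  if (!is.finite(eta)) stop("eta must be finite", call. = FALSE)
  exp(as.numeric(cpp_po_logtheta(mu, eta)))
}

#' Linear predictor of a cell's cluster pair
#'
#' Returns `alpha[r] + beta[c] (+ gamma[r, c])`; the cumulative logit of
#' category `k` for that cell is `mu[k]` minus this value.  Modes with a
#' `"single"` structure contribute 0 through their baseline-zero effect.
#'
#' @param params a [pofm_params()].
#' @param spec the matching [pofm_spec()].
#' @param row_group,col_group group indices (1-based).
#' @return scalar linear predictor.
#' @export
linear_predictor <- function(params, spec, row_group = 1L, col_group = 1L) {
  if (spec$interaction && is.null(params$gamma))
    stop("spec has an interaction but params carry no gamma", call. = FALSE)
  if (row_group < 1 || row_group > length(params$alpha) ||
      col_group < 1 || col_group > length(params$beta))
    stop("group index out of range for this spec", call. = FALSE)
  eta <- params$alpha[row_group] + params$beta[col_group]
  if (spec$interaction) eta <- eta + params$gamma[row_group, col_group]
  eta
}

# GR x GC matrix of linear predictors
eta_matrix <- function(params) {
  eta <- outer(params$alpha, params$beta, "+")
  if (!is.null(params$gamma)) eta <- eta + params$gamma
  eta
}

# GR x GC x q array of log cell probabilities
logtheta_array <- function(params) {
  cpp_logtheta_cube(params$mu, eta_matrix(params))
}
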