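# Ten likelihood-based information criteria for choosing the number of
# clusters.  Notation: l = maximised incomplete-data log-likelihood,
# lc = maximised expected complete-data log-likelihood,
# EN = l - lc (entropy of the fuzzy allocation), nu = parameter count,
# np = number of cells of the response matrix (the total sample size).
# All ten are minimised.

criteria_names <- function() {
  c("aic", "aicc", "aicu", "caic", "bic", "aic3", "clc", "nec", "iclbic",
    "awe")
}

# grid labels: effective number of row / column clusters of a spec
spec_RC <- function(spec, n = NA_integer_, p = NA_integer_) {
  R <- switch(spec$rows, single = 1L, clustered = spec$R, saturated = n)
  C <- switch(spec$cols, single = 1L, clustered = spec$C, saturated = p)
  c(R = R, C = C)
}

#' Information criteria for a fitted model
#'
#' Computes AIC, AICc, AICu, CAIC, BIC, AIC3, CLC, NEC, ICL-BIC and AWE from
#' a fitted model.  The sample size entering every penalty is `np`, the
#' number of cells of the response matrix.  AICc and AICu are undefined
#' (reported `NA`) unless `np > nu + 1`; NEC needs the null-model
#' log-likelihood `l(1)` (the `(single, single)` fit on the same data) and
#' is undefined for the null model itself and when `l - l(1) <= 1e-12`.
#' Entropy-based criteria use `EN = l - lc` in total (row plus column)
#' form.
#'
#' @param fit a [pofm_fit()] result.
#' @param null_loglik maximised log-likelihood of the null model on the same
#'   data (needed for NEC only).
#' @return one-row `data.frame` with the model labels, `nu`, `loglik`,
#'   `loglik_c`, `entropy` and the ten criterion values.
#' @examples
#' sim <- pofm_simulate(pofm_sim_config(n = 20, p = 8, q = 3,
#'                                      alpha = c(0, 2)), seed = 1)
#' fit <- pofm_fit(sim$data, pofm_spec("clustered", "single", R = 2),
#'                 n_starts = 2, seed = 1)
#' pofm_criteria(fit)
#' @export
pofm_criteria <- function(fit, null_loglik = NULL) {
  stopifnot(inherits(fit, "pofm_fit"))
  l <- fit$loglik; lc <- fit$loglik_complete; en <- fit$entropy
  nu <- fit$nu; np <- fit$n * fit$p
  rc <- spec_RC(fit$spec, fit$n, fit$p)

  aic <- -2 * l + 2 * nu
  small_ok <- np > nu + 1
  aicc <- if (small_ok) aic + 2 * nu * (nu + 1) / (np - nu - 1) else NA_real_
  aicu <- if (small_ok) aicc + np * log(np / (np - nu - 1)) else NA_real_
  caic <- -2 * l + nu * (1 + log(np))
  bic <- -2 * l + nu * log(np)
  aic3 <- -2 * l + 3 * nu
  clc <- -2 * l + 2 * en
  is_null <- fit$spec$rows == "single" && fit$spec$cols == "single"
  nec <- if (is_null || is.null(null_loglik) || (l - null_loglik) <= 1e-12)
    NA_real_ else en / (l - null_loglik)
  iclbic <- -2 * lc + nu * log(np)
  awe <- -2 * lc + 2 * nu * (3 / 2 + log(np))

  data.frame(rows = fit$spec$rows, cols = fit$spec$cols,
             R = rc[["R"]], C = rc[["C"]],
             interaction = fit$spec$interaction,
             nu = nu, loglik = l, loglik_flag = fit$loglik_flag,
             loglik_c = lc, entropy = en,
             aic = aic, aicc = aicc, aicu = aicu, caic = caic, bic = bic,
             aic3 = aic3, clc = clc, nec = nec, iclbic = iclbic, awe = awe,
             stringsAsFactors = FALSE)
}

# argmin of one criterion over a criteria table; ties broken towards
# smaller nu, then smaller R, then smaller C; NA rows never win
criteria_argmin <- function(table, criterion) {
  vals <- table[[criterion]]
  if (all(is.na(vals))) return(NA_integer_)
  ord <- order(vals, table$nu, table$R, table$C, na.last = TRUE)
  ord[1]
}

#' Build a grid of additive (bi)clustering model specifications
#'
#' One spec per `(R, C)` pair with `R = 1..Rmax`, `C = 1..Cmax`; `R = 1` or
#' `C = 1` uses the `"single"` structure (so `(1, 1)` is the null model).
#' With `interaction = TRUE`, interaction variants are appended for every
#' pair with both `R > 1` and `C > 1`.
#'
#' @param Rmax,Cmax largest number of row / column clusters.
#' @param interaction also include interaction models?
#' @return list of [pofm_spec()] objects.
#' @export
pofm_spec_grid <- function(Rmax, Cmax, interaction = FALSE) {
  stopifnot(Rmax >= 1, Cmax >= 1)
  grid_spec <- function(R, C, inter) {
    pofm_spec(rows = if (R == 1) "single" else "clustered",
              cols = if (C == 1) "single" else "clustered",
              R = if (R > 1) R, C = if (C > 1) C, interaction = inter)
  }
  specs <- list()
  for (R in seq_len(Rmax))
    for (C in seq_len(Cmax)) {
      specs[[length(specs) + 1L]] <- grid_spec(R, C, FALSE)
      if (interaction && R > 1 && C > 1)
        specs[[length(specs) + 1L]] <- grid_spec(R, C, TRUE)
    }
  specs
}

#' Fit a set of models and select by an information criterion
#'
#' Fits every spec in `specs` (each with `n_starts` EM restarts), assembles
#' the full criteria table, and returns the spec minimising the requested
#' criterion.  The null-model log-likelihood `l(1)` needed by NEC is taken
#' from the `(single, single)` spec if present in the set, otherwise fitted
#' once on the side.  Ties are broken towards smaller `nu`, then smaller
#' `R`, then smaller `C`.
#'
#' @inheritParams pofm_fit
#' @param specs non-empty list of [pofm_spec()] objects (see
#'   [pofm_spec_grid()]).
#' @param criterion one of `"aic"`, `"aicc"`, `"aicu"`, `"caic"`, `"bic"`,
#'   `"aic3"`, `"clc"`, `"nec"`, `"iclbic"`, `"awe"`.
#' @return list with `best_spec`, `best_fit`, `criterion`, the full
#'   `table`, and the list of `fits`.
#' @export
pofm_select <- function(data, specs, criterion = "aic3", q = NULL,
                        n_starts = 10L, max_iter = 500L, tol = 1e-8,
                        seed = 1L) {
  data <- coerce_data(data, q)
  criterion <- match.arg(tolower(criterion), criteria_names())
  if (length(specs) == 0) stop("`specs` must be non-empty", call. = FALSE)
  if (inherits(specs, "pofm_spec")) specs <- list(specs)

  set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max - 1L, length(specs) + 1L)
  fits <- vector("list", length(specs))
  for (i in seq_along(specs))
    fits[[i]] <- pofm_fit(data, specs[[i]], n_starts = n_starts,
                          max_iter = max_iter, tol = tol,
                          seed = fit_seeds[i])

  is_null_spec <- vapply(specs, function(s)
    s$rows == "single" && s$cols == "single", logical(1))
  null_ll <- if (any(is_null_spec)) fits[[which(is_null_spec)[1]]]$loglik
             else pofm_fit(data, pofm_spec("single", "single"),
                           seed = fit_seeds[length(fit_seeds)])$loglik

  table <- do.call(rbind, lapply(fits, pofm_criteria, null_loglik = null_ll))
  idx <- criteria_argmin(table, criterion)
  if (is.na(idx))
    stop("criterion '", criterion, "' is undefined for every fitted model",
         call. = FALSE)
  list(best_spec = specs[[idx]], best_fit = fits[[idx]],
       criterion = criterion, table = table, fits = fits,
       null_loglik = null_ll)
}
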