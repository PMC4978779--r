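#' Specify a proportional-odds mixture model structure
#'
#' A model is described by the structure of each mode and an optional
#' row-cluster by column-cluster interaction:
#' \describe{
#'   \item{`"single"`}{all rows (columns) share one effect, fixed at 0;}
#'   \item{`"clustered"`}{rows (columns) come from a finite mixture with
#'     `R` (`C`) components sharing component-level effects;}
#'   \item{`"saturated"`}{every row (column) carries its own fixed effect,
#'     as in the classical row+column proportional-odds model.}
#' }
#' The `(single, single)` specification is the null model whose only
#' parameters are the `q - 1` cutpoints.
#'
#' @param rows,cols structure of each mode.
#' @param R,C number of mixture components; required when the corresponding
#'   mode is `"clustered"`.  `R = 1` (`C = 1`) is the degenerate one-component
#'   mixture, equivalent to `"single"`.
#' @param interaction add interaction terms `gamma[r, c]` (double
#'   sum-to-zero constrained)?  Requires that neither mode is `"single"`.
#' @return a `pofm_spec` object.
#' @examples
#' pofm_spec("clustered", "clustered", R = 3, C = 2)
#' pofm_spec("single", "single")   # null model
#' @export
pofm_spec <- function(rows = c("single", "clustered", "saturated"),
                      cols = c("single", "clustered", "saturated"),
                      R = NULL, C = NULL, interaction = FALSE) {
  rows <- match.arg(rows)
  cols <- match.arg(cols)
  if (rows == "clustered") {
    if (is.null(R) || R < 1 || R != round(R))
      stop("clustered rows require an integer R >= 1", call. = FALSE)
    R <- as.integer(R)
  } else R <- NULL
  if (cols == "clustered") {
    if (is.null(C) || C < 1 || C != round(C))
      stop("clustered columns require an integer C >= 1", call. = FALSE)
    C <- as.integer(C)
  } else C <- NULL
  if (interaction && (rows == "single" || cols == "single"))
    stop("an interaction requires that neither mode is 'single'",
         call. = FALSE)
  structure(list(rows = rows, cols = cols, R = R, C = C,
                 interaction = isTRUE(interaction)),
            class = "pofm_spec")
}

#' @export
print.pofm_spec <- function(x, ...) {
  lab <- function(mode, k) switch(mode,
    single = "single", saturated = "saturated",
    clustered = sprintf("clustered (%d groups)", k))
  cat("pofm model spec: rows ", lab(x$rows, x$R), ", cols ", lab(x$cols, x$C),
      if (x$interaction) ", with interaction" else ", additive", "\n", sep = "")
  invisible(x)
}

# effective number of row / column groups for given data dimensions
spec_groups <- function(spec, n, p) {
  GR <- switch(spec$rows, single = 1L, clustered = spec$R, saturated = as.integer(n))
  GC <- switch(spec$cols, single = 1L, clustered = spec$C, saturated = as.integer(p))
  list(GR = GR, GC = GC)
}

# validate a spec against data dimensions (fit-time check)
check_spec <- function(spec, n, p) {
  stopifnot(inherits(spec, "pofm_spec"))
  if (spec$rows == "clustered" && spec$R > n)
    stop("R must not exceed the number of rows", call. = FALSE)
  if (spec$cols == "clustered" && spec$C > p)
    stop("C must not exceed the number of columns", call. = FALSE)
  invisible(spec)
}

#' Number of free parameters of a model
#'
#' Counts the cutpoints, identifiable row/column effects, free interaction
#' terms and mixing proportions of a model specification: `q - 1` cutpoints,
#' `GR - 1` row effects and `GC - 1` column effects (the first group of each
#' mode is the baseline), `(GR - 1) (GC - 1)` free interaction cells under
#' the double sum-to-zero constraint, and `R - 1` (`C - 1`) mixing
#' proportions for each clustered mode, where `GR`/`GC` is 1, `R`/`C` or
#' `n`/`p` according to the mode structure.
#'
#' @param spec a [pofm_spec()].
#' @param n,p data dimensions.
#' @param q number of ordered categories.
#' @return integer parameter count.
#' @examples
#' pofm_nparams(pofm_spec("clustered", "clustered", R = 3, C = 2), 99, 100, 4)
#' @export
pofm_nparams <- function(spec, n, p, q) {
  check_spec(spec, n, p)
  g <- spec_groups(spec, n, p)
  nu <- (q - 1L) + (g$GR - 1L) + (g$GC - 1L)
  if (spec$interaction) nu <- nu + (g$GR - 1L) * (g$GC - 1L)
  if (spec$rows == "clustered") nu <- nu + spec$R - 1L
  if (spec$cols == "clustered") nu <- nu + spec$C - 1L
  as.integer(nu)
}

#' Bundle model parameters
#'
#' @param mu strictly increasing vector of `q - 1` cutpoints.
#' @param alpha row-effect vector (length 1, `R` or `n`; `alpha[1] = 0`).
#' @param beta column-effect vector (length 1, `C` or `p`; `beta[1] = 0`).
#' @param gamma interaction matrix with zero row and column sums, or `NULL`.
#' @param pi,kappa mixing proportions of clustered modes, or `NULL`.
#' @return a `pofm_params` list.
#' @export
pofm_params <- function(mu, alpha = 0, beta = 0, gamma = NULL,
                        pi = NULL, kappa = NULL) {
  structure(list(mu = as.numeric(mu), alpha = as.numeric(alpha),
                 beta = as.numeric(beta),
                 gamma = if (!is.null(gamma)) as.matrix(gamma),
                 pi = if (!is.null(pi)) as.numeric(pi),
                 kappa = if (!is.null(kappa)) as.numeric(kappa)),
            class = "pofm_params")
}

#' Check parameter constraints
#'
#' Reports (rather than throws) violations of the parameter constraints:
#' strictly increasing cutpoints, baseline-zero first effects, double
#' sum-to-zero interaction, and simplex mixing proportions.
#'
#' @param params a [pofm_params()] list.
#' @param spec the matching [pofm_spec()] (used to decide which components
#'   must be present); may be `NULL` to check only what is present.
#' @return character vector of violation messages; empty if all hold.
#' @examples
#' validate_params(pofm_params(mu = c(1, 0)))   # out-of-order cutpoints
#' @export
validate_params <- function(params, spec = NULL) {
  v <- character()
  mu <- params$mu
  if (length(mu) < 1 || anyNA(mu))
    v <- c(v, "cutpoints mu are missing")
  else if (length(mu) > 1 && any(diff(mu) <= 0))
    v <- c(v, "cutpoints mu must be strictly increasing")
  if (length(params$alpha) >= 1 && abs(params$alpha[1]) > 1e-10)
    v <- c(v, "identifiability requires alpha[1] = 0")
  if (length(params$beta) >= 1 && abs(params$beta[1]) > 1e-10)
    v <- c(v, "identifiability requires beta[1] = 0")
  if (!is.null(params$gamma)) {
    g <- params$gamma
    if (any(abs(rowSums(g)) > 1e-10) || any(abs(colSums(g)) > 1e-10))
      v <- c(v, "interaction gamma must have zero row and column sums")
  }
  for (nm in c("pi", "kappa")) {
    w <- params[[nm]]
    if (!is.null(w)) {
      if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
        v <- c(v, sprintf(
          "%s must be non-negative mixing proportions summing to 1", nm))
    }
  }
  if (!is.null(spec)) {
    if (spec$interaction && is.null(params$gamma))
      v <- c(v, "spec has an interaction but gamma is absent")
    if (spec$rows == "clustered" && is.null(params$pi))
      v <- c(v, "clustered rows require mixing proportions pi")
    if (spec$cols == "clustered" && is.null(params$kappa))
      v <- c(v, "clustered columns require mixing proportions kappa")
  }
  v
}
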