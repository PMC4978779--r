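# Synthetic ordinal-matrix generation and the two study drivers:
# a model-selection study (how often each criterion recovers the generating
# (R, C)) and a cluster-recovery study (parameter estimates and Rand
# indices against the generating truth).

#' Cutpoints giving equal baseline category probabilities
#'
#' `mu_k = logit(k / q)`, so that a cell with linear predictor 0 (the
#' baseline row and column cluster) has probability `1/q` for each of the
#' `q` categories.
#'
#' @param q number of ordered categories (>= 2).
#' @return strictly increasing cutpoint vector of length `q - 1`.
#' @examples
#' equal_probability_cutpoints(3)   # log(1/2), log(2)
#' @export
equal_probability_cutpoints <- function(q) {
  if (length(q) != 1 || q < 2 || q != round(q))
    stop("`q` must be a single integer >= 2", call. = FALSE)
  stats::qlogis(seq_len(q - 1) / q)
}

#' Describe a generating model for simulation
#'
#' The structure is inferred from the effect vectors: a mode with more than
#' one effect value is clustered (with as many components as effects),
#' otherwise it is single.  Cluster memberships are drawn either as
#' contiguous deterministic blocks of sizes `round(prop * n)` (the last
#' block absorbing the rounding remainder) or i.i.d. multinomially from the
#' mixing proportions.
#'
#' @param n,p,q matrix dimensions and category count.
#' @param alpha,beta true cluster effects (first entry 0).
#' @param gamma optional true interaction matrix (zero row/column sums).
#' @param mu cutpoints; defaults to [equal_probability_cutpoints()].
#' @param pi,kappa mixing / block proportions; default uniform.
#' @param membership `"deterministic_blocks"` or `"multinomial"`.
#' @return a `pofm_sim_config` list.
#' @export
pofm_sim_config <- function(n, p, q, alpha = 0, beta = 0, gamma = NULL,
                            mu = equal_probability_cutpoints(q),
                            pi = NULL, kappa = NULL,
                            membership = c("deterministic_blocks",
                                           "multinomial")) {
  membership <- match.arg(membership)
  R <- length(alpha); C <- length(beta)
  if (is.null(pi)) pi <- rep(1 / R, R)
  if (is.null(kappa)) kappa <- rep(1 / C, C)
  if (length(pi) != R || length(kappa) != C)
    stop("pi/kappa lengths must match the effect vectors", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-8 || abs(sum(kappa) - 1) > 1e-8 ||
      any(pi < 0) || any(kappa < 0))
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  truth <- pofm_params(mu = mu, alpha = alpha, beta = beta, gamma = gamma,
                       pi = if (R > 1) pi, kappa = if (C > 1) kappa)
  bad <- validate_params(truth)
  if (length(bad)) stop(paste(bad, collapse = "; "), call. = FALSE)
  spec <- pofm_spec(rows = if (R > 1) "clustered" else "single",
                    cols = if (C > 1) "clustered" else "single",
                    R = if (R > 1) R, C = if (C > 1) C,
                    interaction = !is.null(gamma))
  structure(list(n = n, p = p, q = as.integer(q), spec = spec,
                 params = truth, pi = pi, kappa = kappa,
                 membership = membership),
            class = "pofm_sim_config")
}

block_labels <- function(size, props, membership) {
  k <- length(props)
  if (k == 1) return(rep(1L, size))
  if (membership == "multinomial")
    return(sample.int(k, size, replace = TRUE, prob = props))
  sizes <- round(props * size)
  sizes[k] <- size - sum(sizes[-k])
  if (any(sizes < 0))
    stop("block proportions incompatible with the mode size", call. = FALSE)
  rep.int(seq_len(k), sizes)
}

#' Simulate an ordinal response matrix from a generating model
#'
#' Each cell is an independent draw from the `q` category probabilities of
#' its row/column cluster pair.  The true partitions are returned for
#' evaluation.  Identical `seed` gives identical output.
#'
#' @param config a [pofm_sim_config()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return list with `data` (an [ordinal_matrix()]), `row_groups`,
#'   `col_groups` and the `config`.
#' @export
pofm_simulate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pofm_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n; p <- config$p; q <- config$q
  rows <- block_labels(n, config$pi, config$membership)
  cols <- block_labels(p, config$kappa, config$membership)
  eta <- eta_matrix(config$params)
  Y <- matrix(0L, n, p)
  for (r in seq_len(nrow(eta)))
    for (c in seq_len(ncol(eta))) {
      cells <- outer(rows == r, cols == c, "&")
      cnt <- sum(cells)
      if (cnt == 0) next
      theta <- po_probs(config$params$mu, eta[r, c])
      Y[cells] <- sample.int(q, cnt, replace = TRUE, prob = theta)
    }
  list(data = ordinal_matrix(Y, q), row_groups = rows, col_groups = cols,
       config = config)
}

#' The five mixing-proportion scenarios of the model-selection study
#'
#' Generating truth `R = 3` row and `C = 2` column clusters; the scenarios
#' vary how balanced the mixing proportions are, from mildly unbalanced
#' through balanced to one row proportion close to zero.
#'
#' @return named list of scenarios, each with elements `pi` and `kappa`.
#' @export
selection_scenarios <- function() {
  list(
    S1 = list(pi = c(0.2, 0.3, 0.5),    kappa = c(0.7, 0.3)),
    S2 = list(pi = rep(1 / 3, 3),       kappa = c(0.5, 0.5)),
    S3 = list(pi = c(0.6, 0.3, 0.1),    kappa = c(0.5, 0.5)),
    S4 = list(pi = c(0.6, 0.3, 0.1),    kappa = c(0.8, 0.2)),
    S5 = list(pi = c(0.85, 0.10, 0.05), kappa = c(0.5, 0.5))
  )
}

# classify a selected (R, C) against the generating truth
classify_selection <- function(R, C, trueR, trueC) {
  if (R == trueR && C == trueC) return("correct")
  if (R <= trueR && C <= trueC) return("under")
  if (R >= trueR && C >= trueC) return("over")
  "other"
}

#' Model-selection recovery study
#'
#' Simulates datasets from the true additive biclustering model under each
#' mixing-proportion scenario, fits the full additive grid
#' `R = 1..Rmax, C = 1..Cmax` with multiple EM restarts, applies all ten
#' information criteria, and tabulates how often each criterion selects the
#' generating `(R, C)`, a smaller model (component-wise `<=` with at least
#' one strict), or a larger one.
#'
#' @param reps simulated datasets per scenario.
#' @param n,p,q data dimensions.
#' @param alpha,beta generating cluster effects.
#' @param mu generating cutpoints.
#' @param Rmax,Cmax grid bounds.
#' @param n_starts EM restarts per fitted model.
#' @param seed master seed; per-replicate seeds are derived by counter so
#'   results do not depend on execution order.
#' @param scenarios list of scenarios (elements `pi`, `kappa`); defaults to
#'   [selection_scenarios()].
#' @param max_iter,tol EM control.
#' @param verbose print progress per scenario?
#' @return list with `per_scenario` (scenario x criterion percentages),
#'   `summary` (percentages averaged across scenarios), `n_datasets`, and
#'   `failures` (fit failures, excluded with count).
#' @export
selection_study <- function(reps = 20L, n = 150L, p = 15L, q = 4L,
                            alpha = c(0, 1, 2), beta = c(0, -1),
                            mu = equal_probability_cutpoints(q),
                            Rmax = 4L, Cmax = 4L, n_starts = 10L, seed = 1L,
                            scenarios = selection_scenarios(),
                            max_iter = 500L, tol = 1e-8, verbose = FALSE) {
  stopifnot(reps >= 1)
  trueR <- length(alpha); trueC <- length(beta)
  crits <- criteria_names()
  specs <- pofm_spec_grid(Rmax, Cmax)
  ns <- length(scenarios)
  if (is.null(names(scenarios))) names(scenarios) <- paste0("S", seq_len(ns))

  set.seed(seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1L, ns * reps * 2L),
                     nrow = ns * reps)
  tallies <- list()
  failures <- 0L
  idx <- 0L
  for (s in seq_len(ns)) {
    sc <- scenarios[[s]]
    config <- pofm_sim_config(n = n, p = p, q = q, alpha = alpha,
                              beta = beta, mu = mu, pi = sc$pi,
                              kappa = sc$kappa, membership = "multinomial")
    counts <- matrix(0L, length(crits), 4L,
                     dimnames = list(crits, c("correct", "under", "over",
                                              "other")))
    used <- 0L
    for (t in seq_len(reps)) {
      idx <- idx + 1L
      sim <- pofm_simulate(config, seed = seed_tab[idx, 1])
      sel <- tryCatch(
        pofm_select(sim$data, specs, criterion = "aic3",
                    n_starts = n_starts, max_iter = max_iter, tol = tol,
                    seed = seed_tab[idx, 2]),
        error = function(e) e)
      if (inherits(sel, "error")) { failures <- failures + 1L; next }
      used <- used + 1L
      for (cr in crits) {
        k <- criteria_argmin(sel$table, cr)
        if (is.na(k)) next
        cls <- classify_selection(sel$table$R[k], sel$table$C[k],
                                  trueR, trueC)
        counts[cr, cls] <- counts[cr, cls] + 1L
      }
    }
    if (verbose)
      message(sprintf("scenario %s: %d/%d datasets used",
                      names(scenarios)[s], used, reps))
    tallies[[s]] <- data.frame(scenario = names(scenarios)[s],
                               criterion = crits,
                               100 * counts / max(used, 1L),
                               n_datasets = used, row.names = NULL)
  }
  per_scenario <- do.call(rbind, tallies)
  summary <- do.call(rbind, lapply(crits, function(cr) {
    rows <- per_scenario[per_scenario$criterion == cr, ]
    data.frame(criterion = cr,
               correct = mean(rows$correct), under = mean(rows$under),
               over = mean(rows$over), other = mean(rows$other))
  }))
  list(per_scenario = per_scenario, summary = summary,
       n_datasets = sum(per_scenario$n_datasets[per_scenario$criterion ==
                                                  crits[1]]),
       failures = failures)
}

#' Cluster-recovery study
#'
#' For each generating configuration, repeatedly simulates a dataset, fits
#' the model with the generating structure, aligns the estimated cluster
#' labels with the truth, and records the effect estimates and the Rand
#' index between the hard posterior partitions and the true partitions.
#'
#' @param configs list of [pofm_sim_config()] objects (a single config is
#'   also accepted).
#' @param reps simulated datasets per configuration.
#' @param n_starts EM restarts per fit.
#' @param seed master seed; per-replicate seeds derived by counter.
#' @param max_iter,tol EM control.
#' @param verbose print progress per configuration?
#' @return list with `summary` (one row per configuration and quantity:
#'   mean and standard error of aligned effect estimates, mean Rand
#'   indices) and `raw` (one row per replicate and quantity).
#' @export
recovery_study <- function(configs, reps = 25L, n_starts = 10L, seed = 1L,
                           max_iter = 500L, tol = 1e-8, verbose = FALSE) {
  stopifnot(reps >= 1)
  if (inherits(configs, "pofm_sim_config")) configs <- list(configs)
  if (is.null(names(configs)))
    names(configs) <- paste0("config", seq_along(configs))
  set.seed(seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1L,
                                length(configs) * reps * 2L),
                     nrow = length(configs) * reps)
  raw <- list()
  idx <- 0L
  for (ci in seq_along(configs)) {
    config <- configs[[ci]]
    truth <- config$params
    R <- length(truth$alpha); C <- length(truth$beta)
    for (t in seq_len(reps)) {
      idx <- idx + 1L
      sim <- pofm_simulate(config, seed = seed_tab[idx, 1])
      fit <- tryCatch(
        pofm_fit(sim$data, config$spec, n_starts = n_starts,
                 max_iter = max_iter, tol = tol, seed = seed_tab[idx, 2]),
        error = function(e) e)
      if (inherits(fit, "error")) next
      est <- align_labels(fit$params, truth)
      vals <- c()
      if (R > 1)
        vals <- c(vals, stats::setNames(est$alpha[-1],
                                        paste0("alpha", 2:R)))
      if (C > 1)
        vals <- c(vals, stats::setNames(est$beta[-1], paste0("beta", 2:C)))
      if (R > 1)
        vals <- c(vals, rand_row = rand_index(
          hard_assignment(fit$posteriors$zhat), sim$row_groups))
      if (C > 1)
        vals <- c(vals, rand_col = rand_index(
          hard_assignment(fit$posteriors$xhat), sim$col_groups))
      raw[[length(raw) + 1L]] <-
        data.frame(config = names(configs)[ci], rep = t,
                   quantity = names(vals), value = unname(vals),
                   row.names = NULL)
    }
    if (verbose) message("finished ", names(configs)[ci])
  }
  raw <- do.call(rbind, raw)
  summary <- do.call(rbind, lapply(split(raw, raw[c("quantity", "config")],
                                         drop = TRUE), function(d)
    data.frame(config = d$config[1], quantity = d$quantity[1],
               mean = mean(d$value),
               se = stats::sd(d$value) / sqrt(nrow(d)),
               reps = nrow(d))))
  rownames(summary) <- NULL
  list(summary = summary, raw = raw)
}
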