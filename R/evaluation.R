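# Partition-agreement metrics and label-alignment utilities used by the
# simulation studies.

#' Hard cluster assignment from fuzzy memberships
#'
#' Argmax per item; exact posterior ties go to the lowest group index.
#' Groups that receive no item are retained in the group count `k`.
#'
#' @param posteriors membership matrix with rows summing to 1.
#' @return integer label vector with attribute `k` (number of groups).
#' @export
hard_assignment <- function(posteriors) {
  M <- as.matrix(posteriors)
  check_posterior_rows(M)
  structure(max.col(M, ties.method = "first"), k = ncol(M))
}

#' Rand index of two partitions
#'
#' Fraction of item pairs on which the partitions agree: a pair counts as
#' concordant when it is co-clustered in both partitions or separated in
#' both.
#'
#' @param a,b label vectors of equal length (>= 2).
#' @return agreement in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2), c(1, 2, 2))   # 1/3
#' @export
rand_index <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("partitions must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("pairwise agreement needs at least 2 items", call. = FALSE)
  tab <- table(a, b)
  ssum <- sum(choose(tab, 2))
  arow <- sum(choose(rowSums(tab), 2))
  bcol <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * ssum - arow - bcol) / total
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (sub in all_permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[sub])
    }
  }
  out
}

align_mode <- function(est_eff, true_eff) {
  perms <- all_permutations(length(est_eff))
  cost <- vapply(perms, function(pm) {
    e <- est_eff[pm] - est_eff[pm][1]
    sum(abs(e - true_eff))
  }, numeric(1))
  perms[[which.min(cost)]]
}

#' Align estimated cluster labels with a reference
#'
#' Resolves label switching before averaging estimates across simulation
#' replicates: row (column) groups are permuted to minimise the total
#' absolute discrepancy between the re-baselined estimated effects and the
#' reference effects, then the baseline-zero constraint is re-imposed by the
#' equivalent cutpoint shift.
#'
#' @param estimate,truth [pofm_params()] lists with matching group counts.
#' @return the permuted `estimate`, with attributes `row_perm` and
#'   `col_perm` recording the permutations applied.
#' @export
align_labels <- function(estimate, truth) {
  if (length(estimate$alpha) != length(truth$alpha) ||
      length(estimate$beta) != length(truth$beta))
    stop("estimate and truth must have matching group counts", call. = FALSE)
  row_perm <- seq_along(estimate$alpha)
  col_perm <- seq_along(estimate$beta)
  if (length(estimate$alpha) > 1) {
    row_perm <- align_mode(estimate$alpha, truth$alpha)
    estimate <- apply_row_perm(estimate, row_perm)
  }
  if (length(estimate$beta) > 1) {
    col_perm <- align_mode(estimate$beta, truth$beta)
    estimate <- apply_col_perm(estimate, col_perm)
  }
  attr(estimate, "row_perm") <- row_perm
  attr(estimate, "col_perm") <- col_perm
  estimate
}
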