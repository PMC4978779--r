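# Independent brute-force oracles.  These deliberately avoid the package's
# computational path: probabilities via plogis differences, mixture sums by
# plain enumeration on tiny instances, pair counting by explicit loops.

# cell probabilities straight from the logistic CDF
oracle_theta <- function(mu, eta) {
  diff(c(0, stats::plogis(mu - eta), 1))
}

# incomplete-data likelihood by enumeration over all joint row x column
# cluster assignments (the full partition sum)
oracle_loglik_joint <- function(Y, mu, alpha, beta, gamma, pi, kappa) {
  n <- nrow(Y); p <- ncol(Y)
  R <- length(alpha); C <- length(beta)
  if (is.null(gamma)) gamma <- matrix(0, R, C)
  row_asg <- as.matrix(expand.grid(rep(list(seq_len(R)), n)))
  col_asg <- as.matrix(expand.grid(rep(list(seq_len(C)), p)))
  total <- 0
  for (ai in seq_len(nrow(row_asg))) {
    ra <- row_asg[ai, ]
    for (bi in seq_len(nrow(col_asg))) {
      ca <- col_asg[bi, ]
      prob <- prod(pi[ra]) * prod(kappa[ca])
      for (i in seq_len(n))
        for (j in seq_len(p)) {
          th <- oracle_theta(mu, alpha[ra[i]] + beta[ca[j]] +
                               gamma[ra[i], ca[j]])
          prob <- prob * th[Y[i, j]]
        }
      total <- total + prob
    }
  }
  log(total)
}

# row-mixture likelihood by enumeration over all row assignments, with the
# column group of every column known (single mode: all group 1)
oracle_loglik_rowmix <- function(Y, mu, alpha, beta, pi,
                                 col_groups = rep(1L, ncol(Y))) {
  n <- nrow(Y); p <- ncol(Y); R <- length(alpha)
  row_asg <- as.matrix(expand.grid(rep(list(seq_len(R)), n)))
  total <- 0
  for (ai in seq_len(nrow(row_asg))) {
    ra <- row_asg[ai, ]
    prob <- prod(pi[ra])
    for (i in seq_len(n))
      for (j in seq_len(p)) {
        th <- oracle_theta(mu, alpha[ra[i]] + beta[col_groups[j]])
        prob <- prob * th[Y[i, j]]
      }
    total <- total + prob
  }
  log(total)
}

# Rand index by looping over every item pair
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  agree / choose(n, 2)
}

# random tiny test instance (data + valid parameters)
random_instance <- function(n, p, q, R, C, seed) {
  set.seed(seed)
  mu <- sort(stats::rnorm(q - 1, sd = 1.2))
  while (any(diff(mu) < 0.05)) mu <- sort(stats::rnorm(q - 1, sd = 1.2))
  alpha <- c(0, stats::rnorm(R - 1))
  beta <- c(0, stats::rnorm(C - 1))
  pi <- as.numeric(stats::rgamma(R, 2)); pi <- pi / sum(pi)
  kappa <- as.numeric(stats::rgamma(C, 2)); kappa <- kappa / sum(kappa)
  Y <- matrix(sample.int(q, n * p, replace = TRUE), n, p)
  list(Y = Y, data = ordinal_matrix(Y, q), mu = mu, alpha = alpha,
       beta = beta, pi = pi, kappa = kappa)
}
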