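// Numerical core for proportional-odds finite-mixture (bi)clustering.
//
// Everything here works in log space: cell log-probabilities come from
// stable differences of logistic CDFs, mixture sums use log-sum-exp, and
// the M-step maximises the weighted complete-data log-likelihood with a
// Newton line-search on an unconstrained reparameterisation
// (cutpoints as first value + log-increments, interaction as its free
// (R-1)x(C-1) block).

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG_FLOOR = -745.0;   // ~ log(.Machine$double.xmin)
static const double MIX_FLOOR = 1e-10;    // floor inside log(pi), log(kappa)

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log cell probabilities of the cumulative-logit model for one linear
// predictor eta: theta_k = F(mu_k - eta) - F(mu_{k-1} - eta), F logistic.
static void po_logtheta_one(const arma::vec& mu, double eta, double* out) {
  const int q = (int) mu.n_elem + 1;
  out[0] = -log1pexp_(-(mu[0] - eta));            // log F(mu_1 - eta)
  for (int k = 1; k < q - 1; ++k) {
    double a = mu[k] - eta, b = mu[k - 1] - eta;  // a > b
    double d = b - a;                             // < 0
    double lt;
    if (d > -1e-14) {
      lt = LOG_FLOOR;
    } else {
      lt = a + std::log1p(-std::exp(d)) - log1pexp_(a) - log1pexp_(b);
    }
    out[k] = std::max(lt, LOG_FLOOR);
  }
  out[q - 1] = -log1pexp_(mu[q - 2] - eta);       // log(1 - F(mu_{q-1} - eta))
}

// [[Rcpp::export]]
arma::vec cpp_po_logtheta(const arma::vec& mu, double eta) {
  arma::vec out(mu.n_elem + 1);
  po_logtheta_one(mu, eta, out.memptr());
  return out;
}

// GR x GC x q cube of log cell probabilities for a grid of linear predictors.
// [[Rcpp::export]]
arma::cube cpp_logtheta_cube(const arma::vec& mu, const arma::mat& eta) {
  const int GR = eta.n_rows, GC = eta.n_cols, q = (int) mu.n_elem + 1;
  arma::cube L(GR, GC, q);
  std::vector<double> buf(q);
  for (int r = 0; r < GR; ++r)
    for (int c = 0; c < GC; ++c) {
      po_logtheta_one(mu, eta(r, c), buf.data());
      for (int k = 0; k < q; ++k) L(r, c, k) = buf[k];
    }
  return L;
}

static inline double logsumexp_row(const arma::rowvec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (arma::uword i = 0; i < v.n_elem; ++i) s += std::exp(v(i) - m);
  return m + std::log(s);
}

// flatten the GR x GC x q cube to GR x (GC*q) with column index k*GC + c
static arma::mat flatten_L_rows(const arma::cube& L) {
  const int GR = (int) L.n_rows, GC = (int) L.n_cols, q = (int) L.n_slices;
  arma::mat M(GR, GC * q);
  for (int k = 0; k < q; ++k)
    for (int c = 0; c < GC; ++c)
      for (int r = 0; r < GR; ++r) M(r, k * GC + c) = L(r, c, k);
  return M;
}

// flatten to GC x (GR*q) with column index k*GR + r
static arma::mat flatten_L_cols(const arma::cube& L) {
  const int GR = (int) L.n_rows, GC = (int) L.n_cols, q = (int) L.n_slices;
  arma::mat M(GC, GR * q);
  for (int k = 0; k < q; ++k)
    for (int r = 0; r < GR; ++r)
      for (int c = 0; c < GC; ++c) M(c, k * GR + r) = L(r, c, k);
  return M;
}

// U_{i, k*GC+c} = sum_j X_jc I(y_ij = k)
static arma::mat stat_rows(const IntegerMatrix& Y, int q, const arma::mat& X) {
  const int n = Y.nrow(), p = Y.ncol();
  const int GC = (int) X.n_cols;
  arma::mat U(n, GC * q, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    const double* xj = X.colptr(0) + j;   // X(j, c) = colptr(c)[j]
    for (int i = 0; i < n; ++i) {
      int k = Y(i, j) - 1;
      double* u = U.colptr(k * GC) + i;
      for (int c = 0; c < GC; ++c) u[(size_t) c * n] += xj[(size_t) c * p];
    }
  }
  return U;
}

// V_{j, k*GR+r} = sum_i Z_ir I(y_ij = k)
static arma::mat stat_cols(const IntegerMatrix& Y, int q, const arma::mat& Z) {
  const int n = Y.nrow(), p = Y.ncol();
  const int GR = (int) Z.n_cols;
  arma::mat V(p, GR * q, arma::fill::zeros);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      int k = Y(i, j) - 1;
      double* v = V.colptr(k * GR) + j;
      const double* zi = Z.colptr(0) + i;
      for (int r = 0; r < GR; ++r) v[(size_t) r * p] += zi[(size_t) r * n];
    }
  return V;
}

// normalise log-weight rows in place to probabilities; returns the summed
// log normalisers (a log-sum-exp per row)
static double normalise_log_rows(arma::mat& M, const arma::vec& logw) {
  const int n = (int) M.n_rows, K = (int) M.n_cols;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = -std::numeric_limits<double>::infinity();
    for (int k = 0; k < K; ++k) {
      M(i, k) += logw(k);
      if (M(i, k) > m) m = M(i, k);
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(M(i, k) - m);
    double norm = m + std::log(s);
    total += norm;
    for (int k = 0; k < K; ++k) M(i, k) = std::exp(M(i, k) - norm);
  }
  return total;
}

// Row-membership update: log zhat_ir = log pi_r + sum_{c,k} U_ick L_rck,
// normalised over r in log space.  When X encodes known column groups
// (single/saturated modes) the returned `loglik` is the exact row-mixture
// incomplete-data log-likelihood.
// [[Rcpp::export]]
List cpp_estep_rows(const IntegerMatrix& Y, int q, const arma::mat& X,
                    const arma::cube& L, const arma::vec& logpi) {
  arma::mat Z = stat_rows(Y, q, X) * flatten_L_rows(L).t();
  double ll = normalise_log_rows(Z, logpi);
  return List::create(_["post"] = Z, _["loglik"] = ll);
}

// Column-membership update, symmetric to cpp_estep_rows.
// [[Rcpp::export]]
List cpp_estep_cols(const IntegerMatrix& Y, int q, const arma::mat& Z,
                    const arma::cube& L, const arma::vec& logkappa) {
  arma::mat X = stat_cols(Y, q, Z) * flatten_L_cols(L).t();
  double ll = normalise_log_rows(X, logkappa);
  return List::create(_["post"] = X, _["loglik"] = ll);
}

// Fused two-mode E-step: alternate the row and column mean-field updates
// until the largest membership change drops below `tol` or `max_cycles`
// cycles have run.  `xnorm` is the summed column log-normalisers of the
// last column update (used for the variational bound).
// [[Rcpp::export]]
List cpp_estep_twomode(const IntegerMatrix& Y, int q, const arma::mat& Z0,
                       const arma::mat& X0, const arma::cube& L,
                       const arma::vec& logpi, const arma::vec& logkappa,
                       int max_cycles, double tol) {
  arma::mat Lr = flatten_L_rows(L).t();   // (GC*q) x GR
  arma::mat Lc = flatten_L_cols(L).t();   // (GR*q) x GC
  arma::mat Z = Z0, X = X0;
  double xnorm = 0.0;
  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    arma::mat Znew = stat_rows(Y, q, X) * Lr;
    normalise_log_rows(Znew, logpi);
    arma::mat Xnew = stat_cols(Y, q, Znew) * Lc;
    xnorm = normalise_log_rows(Xnew, logkappa);
    double delta = std::max(arma::abs(Znew - Z).max(),
                            arma::abs(Xnew - X).max());
    Z = std::move(Znew);
    X = std::move(Xnew);
    if (delta < tol) break;
  }
  return List::create(_["zhat"] = Z, _["xhat"] = X, _["xnorm"] = xnorm);
}

// W_rck = sum_{ij} Z_ir X_jc I(y_ij = k): sufficient statistics of the
// weighted multinomial that the M-step maximises.  Assembled per column:
// W(r,c,k) += X(j,c) * M_j(r,k) with M_j(r,k) = sum_i Z_ir I(y_ij = k).
// [[Rcpp::export]]
arma::cube cpp_weight_cube(const IntegerMatrix& Y, int q,
                           const arma::mat& Z, const arma::mat& X) {
  const int n = Y.nrow(), p = Y.ncol();
  const int GR = (int) Z.n_cols, GC = (int) X.n_cols;
  arma::cube W(GR, GC, q, arma::fill::zeros);
  arma::mat M(GR, q);
  for (int j = 0; j < p; ++j) {
    M.zeros();
    for (int i = 0; i < n; ++i) {
      int k = Y(i, j) - 1;
      const double* zi = Z.colptr(0) + i;
      double* m = M.colptr(k);
      for (int r = 0; r < GR; ++r) m[r] += zi[(size_t) r * n];
    }
    for (int k = 0; k < q; ++k)
      for (int c = 0; c < GC; ++c) {
        double x = X(j, c);
        if (x == 0.0) continue;
        const double* m = M.colptr(k);
        for (int r = 0; r < GR; ++r) W(r, c, k) += x * m[r];
      }
  }
  return W;
}

// ---------------------------------------------------------------------------
// M-step: maximise g(par) = sum_{rck} W_rck log theta_k(mu, eta_rc) over the
// unconstrained vector
//   x = (mu_1, log(mu_2-mu_1), ..., alpha_{2..GR}, beta_{2..GC}, gamma free)
// gamma's free block is (GR-1)x(GC-1); remaining entries follow from the
// double sum-to-zero constraints.

struct MstepLayout {
  int q, GR, GC;
  bool row_eff, col_eff, inter;
  int npar() const {
    return (q - 1) + (row_eff ? GR - 1 : 0) + (col_eff ? GC - 1 : 0) +
           (inter ? (GR - 1) * (GC - 1) : 0);
  }
};

static void unpack(const arma::vec& x, const MstepLayout& ly,
                   arma::vec& mu, arma::vec& alpha, arma::vec& beta,
                   arma::mat& gamma) {
  int idx = 0;
  mu.set_size(ly.q - 1);
  mu(0) = x(idx++);
  for (int k = 1; k < ly.q - 1; ++k) mu(k) = mu(k - 1) + std::exp(x(idx++));
  alpha.zeros(ly.GR);
  if (ly.row_eff) for (int r = 1; r < ly.GR; ++r) alpha(r) = x(idx++);
  beta.zeros(ly.GC);
  if (ly.col_eff) for (int c = 1; c < ly.GC; ++c) beta(c) = x(idx++);
  gamma.zeros(ly.GR, ly.GC);
  if (ly.inter) {
    for (int r = 1; r < ly.GR; ++r)
      for (int c = 1; c < ly.GC; ++c) gamma(r, c) = x(idx++);
    for (int r = 1; r < ly.GR; ++r)
      gamma(r, 0) = -arma::accu(gamma(r, arma::span(1, ly.GC - 1)));
    for (int c = 0; c < ly.GC; ++c) {
      double s = 0.0;
      for (int r = 1; r < ly.GR; ++r) s += gamma(r, c);
      gamma(0, c) = -s;
    }
  }
}

static arma::vec pack(const MstepLayout& ly, const arma::vec& mu,
                      const arma::vec& alpha, const arma::vec& beta,
                      const arma::mat& gamma) {
  arma::vec x(ly.npar());
  int idx = 0;
  x(idx++) = mu(0);
  for (int k = 1; k < ly.q - 1; ++k) {
    double d = mu(k) - mu(k - 1);
    x(idx++) = std::log(std::max(d, 1e-8));
  }
  if (ly.row_eff) for (int r = 1; r < ly.GR; ++r) x(idx++) = alpha(r);
  if (ly.col_eff) for (int c = 1; c < ly.GC; ++c) x(idx++) = beta(c);
  if (ly.inter)
    for (int r = 1; r < ly.GR; ++r)
      for (int c = 1; c < ly.GC; ++c) x(idx++) = gamma(r, c);
  return x;
}

// value and (analytic) gradient of the weighted complete-data log-likelihood
static double obj_grad(const arma::vec& x, const arma::cube& W,
                       const MstepLayout& ly, arma::vec* grad) {
  const int q = ly.q, GR = ly.GR, GC = ly.GC;
  arma::vec mu, alpha, beta;
  arma::mat gamma;
  unpack(x, ly, mu, alpha, beta, gamma);

  arma::vec gmu(q - 1, arma::fill::zeros);
  arma::mat geta(GR, GC, arma::fill::zeros);
  std::vector<double> lth(q), th(q), dens(q - 1), t(q);
  double val = 0.0;

  for (int r = 0; r < GR; ++r)
    for (int c = 0; c < GC; ++c) {
      double eta = alpha(r) + beta(c) + gamma(r, c);
      po_logtheta_one(mu, eta, lth.data());
      for (int k = 0; k < q; ++k) th[k] = std::exp(lth[k]);
      for (int m = 0; m < q - 1; ++m) {
        double a = mu(m) - eta;
        dens[m] = std::exp(-log1pexp_(-a) - log1pexp_(a));  // F(1-F)
      }
      bool any = false;
      for (int k = 0; k < q; ++k) {
        double w = W(r, c, k);
        if (w != 0.0) { val += w * lth[k]; any = true; }
        t[k] = (w == 0.0) ? 0.0 : w / std::max(th[k], 1e-300);
      }
      if (!grad || !any) continue;
      double ge = 0.0;
      for (int m = 0; m < q - 1; ++m) {
        double g = dens[m] * (t[m] - t[m + 1]);
        gmu(m) += g;
        ge -= g;
      }
      geta(r, c) = ge;
    }

  if (grad) {
    arma::vec& g = *grad;
    g.zeros(ly.npar());
    int idx = 0;
    // mu chain rule through the log-increment transform
    double cum = arma::accu(gmu);
    g(idx++) = cum;                       // d/d mu_1 hits every mu_k
    for (int k = 1; k < q - 1; ++k) {
      double s = 0.0;
      for (int m = k; m < q - 1; ++m) s += gmu(m);
      g(idx++) = s * std::exp(x(k));      // x(k) = log increment k
    }
    if (ly.row_eff)
      for (int r = 1; r < GR; ++r) g(idx++) = arma::accu(geta.row(r));
    if (ly.col_eff)
      for (int c = 1; c < GC; ++c) g(idx++) = arma::accu(geta.col(c));
    if (ly.inter)
      for (int r = 1; r < GR; ++r)
        for (int c = 1; c < GC; ++c)
          g(idx++) = geta(r, c) - geta(r, 0) - geta(0, c) + geta(0, 0);
  }
  return val;
}

// Newton-type ascent with finite-difference Hessian of the analytic gradient,
// Levenberg damping and backtracking line search.  Guaranteed never to
// return a point with lower objective than the warm start.
// [[Rcpp::export]]
List cpp_mstep_newton(const arma::cube& W, int q, bool row_eff, bool col_eff,
                      bool inter, const arma::vec& mu0, const arma::vec& alpha0,
                      const arma::vec& beta0, const arma::mat& gamma0,
                      int max_iter = 100, double grad_tol = 1e-7,
                      double step_tol = 1e-11) {
  MstepLayout ly;
  ly.q = q; ly.GR = (int) W.n_rows; ly.GC = (int) W.n_cols;
  ly.row_eff = row_eff; ly.col_eff = col_eff; ly.inter = inter;
  const int np = ly.npar();

  arma::vec x = pack(ly, mu0, alpha0, beta0, gamma0);
  arma::vec grad(np), gtmp(np);
  double f = obj_grad(x, W, ly, &grad);
  int it = 0;
  bool converged = false;

  for (it = 0; it < max_iter; ++it) {
    double scale = 1.0 + std::fabs(f);
    if (arma::norm(grad, "inf") < grad_tol * scale) { converged = true; break; }

    // forward-difference Hessian of the analytic gradient
    arma::mat H(np, np);
    for (int i = 0; i < np; ++i) {
      double h = 1e-6 * (1.0 + std::fabs(x(i)));
      arma::vec xh = x; xh(i) += h;
      obj_grad(xh, W, ly, &gtmp);
      H.col(i) = (gtmp - grad) / h;
    }
    H = 0.5 * (H + H.t());

    double dmean = arma::mean(arma::abs(H.diag()));
    if (!std::isfinite(dmean) || dmean <= 0) dmean = 1.0;
    arma::vec s;
    bool ok = false;
    double lambda = 0.0;
    for (int tr = 0; tr < 12; ++tr) {
      arma::mat A = -H + lambda * arma::eye(np, np);
      ok = arma::solve(s, A, grad, arma::solve_opts::no_approx);
      if (ok && arma::dot(s, grad) > 1e-12 * arma::norm(s) * arma::norm(grad))
        break;
      ok = false;
      lambda = (lambda == 0.0) ? 1e-6 * dmean : lambda * 10.0;
    }
    if (!ok) s = grad / std::max(arma::norm(grad), 1e-12);

    // backtracking line search on the ascent direction
    double step = 1.0, fnew = f;
    arma::vec xnew;
    bool improved = false;
    for (int ls = 0; ls < 50; ++ls) {
      xnew = x + step * s;
      fnew = obj_grad(xnew, W, ly, nullptr);
      if (std::isfinite(fnew) && fnew > f) { improved = true; break; }
      step *= 0.5;
    }
    if (!improved) { converged = true; break; }
    x = xnew;
    double gain = fnew - f;
    f = obj_grad(x, W, ly, &grad);
    if (gain < step_tol * scale) { converged = true; break; }
  }

  arma::vec mu, alpha, beta;
  arma::mat gamma;
  unpack(x, ly, mu, alpha, beta, gamma);
  return List::create(_["mu"] = mu, _["alpha"] = alpha, _["beta"] = beta,
                      _["gamma"] = gamma, _["value"] = f,
                      _["iterations"] = it, _["converged"] = converged);
}

// value of the weighted complete-data log-likelihood at given parameters
// [[Rcpp::export]]
double cpp_weighted_loglik(const arma::cube& W, const arma::vec& mu,
                           const arma::vec& alpha, const arma::vec& beta,
                           const arma::mat& gamma) {
  const int GR = (int) W.n_rows, GC = (int) W.n_cols, q = (int) W.n_slices;
  std::vector<double> lth(q);
  double val = 0.0;
  for (int r = 0; r < GR; ++r)
    for (int c = 0; c < GC; ++c) {
      po_logtheta_one(mu, alpha(r) + beta(c) + gamma(r, c), lth.data());
      for (int k = 0; k < q; ++k) {
        double w = W(r, c, k);
        if (w != 0.0) val += w * lth[k];
      }
    }
  return val;
}

// ---------------------------------------------------------------------------
// Exact incomplete-data log-likelihood of the biclustering model: sums over
// every assignment of the p columns to C clusters (the rows are marginalised
// exactly inside each term).  Columns are enumerated in reflected mixed-radix
// Gray order so that consecutive assignments differ in a single column,
// keeping the per-assignment update O(n R).

// [[Rcpp::export]]
double cpp_loglik_bicluster_exact(const IntegerMatrix& Y, int q,
                                  const arma::vec& mu, const arma::vec& alpha,
                                  const arma::vec& beta, const arma::mat& gamma,
                                  const arma::vec& logpi,
                                  const arma::vec& logkappa) {
  const int n = Y.nrow(), p = Y.ncol();
  const int R = (int) alpha.n_elem, C = (int) beta.n_elem;
  arma::cube L(R, C, q);
  std::vector<double> buf(q);
  for (int r = 0; r < R; ++r)
    for (int c = 0; c < C; ++c) {
      po_logtheta_one(mu, alpha(r) + beta(c) + gamma(r, c), buf.data());
      for (int k = 0; k < q; ++k) L(r, c, k) = buf[k];
    }

  // S(i,r) = sum_j L(r, a_j, y_ij) under the current assignment a
  arma::mat S(n, R, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j)
      for (int r = 0; r < R; ++r) S(i, r) += L(r, 0, Y(i, j) - 1);
  double prior = p * logkappa(0);

  if (C == 1) {   // single assignment: the plain row mixture
    double term = prior;
    arma::rowvec lz1(R);
    for (int i = 0; i < n; ++i) {
      for (int r = 0; r < R; ++r) lz1(r) = logpi(r) + S(i, r);
      term += logsumexp_row(lz1);
    }
    return term;
  }

  std::vector<int> a(p, 0), d(p, 1), foc(p + 1);
  for (int j = 0; j <= p; ++j) foc[j] = j;

  double acc = -std::numeric_limits<double>::infinity();
  const double* Sm = S.memptr();          // S(i, r) = Sm[r * n + i]
  const double* Lm = L.memptr();          // L(r, c, k) = Lm[k*R*C + c*R + r]
  std::vector<double> lp(R), lz(R);
  for (int r = 0; r < R; ++r) lp[r] = logpi(r);
  for (;;) {
    // visit current assignment
    double term = prior;
    for (int i = 0; i < n; ++i) {
      double m = -std::numeric_limits<double>::infinity();
      for (int r = 0; r < R; ++r) {
        double v = lp[r] + Sm[(size_t) r * n + i];
        lz[r] = v;
        if (v > m) m = v;
      }
      double s = 0.0;
      for (int r = 0; r < R; ++r) s += std::exp(lz[r] - m);
      term += m + std::log(s);
    }
    if (term > acc) {
      acc = term + log1pexp_(acc - term);
    } else {
      acc = acc + log1pexp_(term - acc);
    }

    // next reflected Gray step
    int j = foc[0];
    foc[0] = 0;
    if (j == p) break;
    int cold = a[j];
    int cnew = cold + d[j];
    a[j] = cnew;
    prior += logkappa(cnew) - logkappa(cold);
    double* Sw = S.memptr();
    for (int i = 0; i < n; ++i) {
      size_t k = (size_t) (Y(i, j) - 1);
      const double* Ldiff_new = Lm + k * R * C + (size_t) cnew * R;
      const double* Ldiff_old = Lm + k * R * C + (size_t) cold * R;
      for (int r = 0; r < R; ++r)
        Sw[(size_t) r * n + i] += Ldiff_new[r] - Ldiff_old[r];
    }
    if (cnew == 0 || cnew == C - 1) {
      d[j] = -d[j];
      foc[j] = foc[j + 1];
      foc[j + 1] = j + 1;
    }
  }
  return acc;
}
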