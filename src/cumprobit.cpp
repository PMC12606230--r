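// Cumulative-probit mixed model internals.
//
// The latent-variable model: P(y <= k | u) = Phi(tau_k - x'beta - z'u),
// y in 1..4, thresholds tau1 < tau2 < tau3, no global intercept (absorbed
// by the thresholds). Thresholds are passed unconstrained as
// (t1, g2, g3) with tau = (t1, t1 + exp(g2), t1 + exp(g2) + exp(g3)).
//
// Scalar random intercepts are integrated out by adaptive Gauss-Hermite
// quadrature; the vector random effect of the full-random-slopes model by
// a Laplace approximation with per-subject Newton mode finding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;
static const double INV_SQRT_2 = 0.7071067811865476;
static const double INV_SQRT_2PI = 0.3989422804014327;

static inline double phi_pdf(double x) {
  return INV_SQRT_2PI * std::exp(-0.5 * x * x);
}
// Phi(x) via erfc: accurate in both tails, much faster than pnorm
static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x * INV_SQRT_2);
}
static inline double phi_sf(double x) { // upper tail
  return 0.5 * std::erfc(x * INV_SQRT_2);
}

struct CellDeriv {
  double ll;      // log P(y | eta)
  double d1;      // d ll / d eta
  double d2;      // d^2 ll / d eta^2
  double dtau[3]; // d ll / d tau_j
};

// per-observation log-probability and derivatives for category y (1..4)
static inline CellDeriv cell(const double eta, const int y,
                             const double *tau, bool want_d2) {
  CellDeriv out;
  out.dtau[0] = out.dtau[1] = out.dtau[2] = 0.0;
  double a = (y < 4) ? tau[y - 1] - eta : R_PosInf;
  double b = (y > 1) ? tau[y - 2] - eta : R_NegInf;
  double p;
  if (y == 4) {
    p = phi_sf(b);
  } else if (y == 1) {
    p = phi_cdf(a);
  } else if (a + b > 0.0) { // both cut points to the right: use upper tails
    p = phi_sf(b) - phi_sf(a);
  } else {
    p = phi_cdf(a) - phi_cdf(b);
  }
  if (p < 1e-300) p = 1e-300;
  double fa = (y < 4) ? phi_pdf(a) : 0.0;
  double fb = (y > 1) ? phi_pdf(b) : 0.0;
  out.ll = std::log(p);
  out.d1 = (fb - fa) / p;
  if (want_d2) {
    double afa = (y < 4) ? a * fa : 0.0;
    double bfb = (y > 1) ? b * fb : 0.0;
    out.d2 = (bfb - afa) / p - out.d1 * out.d1;
  } else {
    out.d2 = 0.0;
  }
  if (y < 4) out.dtau[y - 1] += fa / p;
  if (y > 1) out.dtau[y - 2] -= fb / p;
  return out;
}

static inline void unpack_tau(const double *theta, double *tau,
                              double *e2, double *e3) {
  *e2 = std::exp(theta[1]);
  *e3 = std::exp(theta[2]);
  tau[0] = theta[0];
  tau[1] = theta[0] + *e2;
  tau[2] = theta[0] + *e2 + *e3;
}

// Per-subject joint log-likelihood in u (scalar intercept) with first and
// second derivatives of the data part.
static void subj_ll_scalar(const arma::vec &eta0, const IntegerVector &y,
                           int lo, int len, const double *tau, double u,
                           double &ll, double &d1, double &d2) {
  ll = 0.0; d1 = 0.0; d2 = 0.0;
  for (int i = lo; i < lo + len; ++i) {
    CellDeriv c = cell(eta0[i] + u, y[i], tau, true);
    ll += c.ll;
    d1 += c.d1;
    d2 += c.d2;
  }
}

// Newton mode and curvature of ll_s(u) - u^2 / (2 sigma^2) per subject.
// [[Rcpp::export]]
List cp_adapt_scalar(NumericVector theta, IntegerVector y,
                     NumericMatrix X, IntegerVector sub_start,
                     IntegerVector sub_len, NumericVector u0) {
  const int p = X.ncol();
  const int S = sub_start.size();
  double tau[3], e2, e3;
  unpack_tau(theta.begin(), tau, &e2, &e3);
  arma::vec beta(p);
  for (int j = 0; j < p; ++j) beta[j] = theta[3 + j];
  const double sigma = std::exp(theta[3 + p]);
  const arma::mat Xm(X.begin(), X.nrow(), p, false);
  arma::vec eta0 = Xm * beta;

  NumericVector uhat(S), shat(S);
  for (int s = 0; s < S; ++s) {
    double u = u0[s];
    double ll, d1, d2;
    for (int it = 0; it < 100; ++it) {
      subj_ll_scalar(eta0, y, sub_start[s], sub_len[s], tau, u, ll, d1, d2);
      double g = d1 - u / (sigma * sigma);
      double h = d2 - 1.0 / (sigma * sigma); // < 0 (log-concave)
      double step = -g / h;
      if (std::fabs(step) > 5.0) step = step > 0 ? 5.0 : -5.0;
      u += step;
      if (std::fabs(step) < 1e-10) break;
    }
    subj_ll_scalar(eta0, y, sub_start[s], sub_len[s], tau, u, ll, d1, d2);
    uhat[s] = u;
    shat[s] = 1.0 / std::sqrt(-(d2 - 1.0 / (sigma * sigma)));
  }
  return List::create(_["uhat"] = uhat, _["shat"] = shat);
}

// Fixed-node AGHQ marginal negative log-likelihood and exact gradient.
// uq: S x Q matrix of node locations; logpref: S x Q matrix of
// log(w_q) + z_q^2 + log(sqrt(2) * shat_s) (theta-independent prefactors).
// [[Rcpp::export]]
List cp_aghq_nll(NumericVector theta, IntegerVector y, NumericMatrix X,
                 IntegerVector sub_start, IntegerVector sub_len,
                 NumericMatrix uq, NumericMatrix logpref, bool want_grad) {
  const int p = X.ncol();
  const int S = sub_start.size();
  const int Q = uq.ncol();
  const int K = 3 + p + 1; // t1, g2, g3, beta, log sigma
  double tau[3], e2, e3;
  unpack_tau(theta.begin(), tau, &e2, &e3);
  arma::vec beta(p);
  for (int j = 0; j < p; ++j) beta[j] = theta[3 + j];
  const double lsig = theta[3 + p];
  const double sigma = std::exp(lsig);
  const arma::mat Xm(X.begin(), X.nrow(), p, false);
  arma::vec eta0 = Xm * beta;

  double nll = 0.0;
  arma::vec grad(K, arma::fill::zeros);
  arma::vec la(Q);
  arma::mat gq; // Q x K per-node gradient contributions
  if (want_grad) gq.set_size(Q, K);

  for (int s = 0; s < S; ++s) {
    const int lo = sub_start[s], len = sub_len[s];
    for (int q = 0; q < Q; ++q) {
      const double u = uq(s, q);
      double ll = 0.0;
      double dt1 = 0.0, dt2 = 0.0, dt3 = 0.0;
      arma::vec db(p, arma::fill::zeros);
      for (int i = lo; i < lo + len; ++i) {
        CellDeriv c = cell(eta0[i] + u, y[i], tau, false);
        ll += c.ll;
        if (want_grad) {
          dt1 += c.dtau[0]; dt2 += c.dtau[1]; dt3 += c.dtau[2];
          for (int j = 0; j < p; ++j) db[j] += c.d1 * Xm(i, j);
        }
      }
      // prior factor phi(u; 0, sigma)
      la[q] = logpref(s, q) + ll - LOG_SQRT_2PI - lsig -
              u * u / (2.0 * sigma * sigma);
      if (want_grad) {
        gq(q, 0) = dt1 + dt2 + dt3;
        gq(q, 1) = e2 * (dt2 + dt3);
        gq(q, 2) = e3 * dt3;
        for (int j = 0; j < p; ++j) gq(q, 3 + j) = db[j];
        gq(q, 3 + p) = -1.0 + u * u / (sigma * sigma);
      }
    }
    double m = la.max();
    double sum = 0.0;
    for (int q = 0; q < Q; ++q) sum += std::exp(la[q] - m);
    nll -= m + std::log(sum);
    if (want_grad) {
      for (int q = 0; q < Q; ++q) {
        double w = std::exp(la[q] - m) / sum;
        for (int k = 0; k < K; ++k) grad[k] -= w * gq(q, k);
      }
    }
  }
  return List::create(_["nll"] = nll,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// Laplace-approximate marginal negative log-likelihood for a q-dimensional
// correlated random effect. theta = (t1, g2, g3, beta[p], lvec) where lvec
// fills the lower triangle of the Cholesky factor L of Sigma column-wise
// with log-diagonal entries. U0 holds warm-start modes (S x q), updated
// modes are returned.
// [[Rcpp::export]]
List cp_laplace_nll(NumericVector theta, IntegerVector y, NumericMatrix X,
                    NumericMatrix Z, IntegerVector sub_start,
                    IntegerVector sub_len, NumericMatrix U0) {
  const int p = X.ncol();
  const int q = Z.ncol();
  const int S = sub_start.size();
  double tau[3], e2, e3;
  unpack_tau(theta.begin(), tau, &e2, &e3);
  arma::vec beta(p);
  for (int j = 0; j < p; ++j) beta[j] = theta[3 + j];
  arma::mat L(q, q, arma::fill::zeros);
  int idx = 3 + p;
  for (int j = 0; j < q; ++j)
    for (int i = j; i < q; ++i) {
      double v = theta[idx++];
      L(i, j) = (i == j) ? std::exp(v) : v;
    }
  arma::mat Sigma = L * L.t();
  arma::mat Sigma_inv = arma::inv_sympd(Sigma);
  double logdet_Sigma = 2.0 * arma::sum(arma::log(L.diag()));

  const arma::mat Xm(X.begin(), X.nrow(), p, false);
  const arma::mat Zm(Z.begin(), Z.nrow(), q, false);
  arma::vec eta0 = Xm * beta;

  NumericMatrix Uout(S, q);
  double nll = 0.0;
  bool ok = true;

  for (int s = 0; s < S; ++s) {
    const int lo = sub_start[s], len = sub_len[s];
    arma::vec u(q);
    for (int j = 0; j < q; ++j) u[j] = U0(s, j);

    auto joint = [&](const arma::vec &uu, arma::vec *g, arma::mat *H) {
      double ll = 0.0;
      if (g) g->zeros(q);
      if (H) H->zeros(q, q);
      for (int i = lo; i < lo + len; ++i) {
        arma::rowvec z = Zm.row(i);
        double eta = eta0[i] + arma::dot(z, uu);
        CellDeriv c = cell(eta, y[i], tau, H != nullptr);
        ll += c.ll;
        if (g) *g += c.d1 * z.t();
        if (H) *H += c.d2 * (z.t() * z);
      }
      ll -= 0.5 * arma::as_scalar(uu.t() * Sigma_inv * uu);
      if (g) *g -= Sigma_inv * uu;
      if (H) *H -= Sigma_inv;
      return ll;
    };

    arma::vec g(q);
    arma::mat H(q, q);
    double h0 = joint(u, &g, &H);
    for (int it = 0; it < 100; ++it) {
      arma::vec step;
      bool solved = arma::solve(step, -H, g, arma::solve_opts::likely_sympd);
      if (!solved) { ok = false; break; }
      double slen = arma::norm(step);
      if (slen > 10.0) step *= 10.0 / slen;
      double t = 1.0;
      double h1 = joint(u + step, nullptr, nullptr);
      int halves = 0;
      while (h1 < h0 - 1e-12 && halves < 30) { // backtrack on decrease
        t *= 0.5;
        h1 = joint(u + t * step, nullptr, nullptr);
        ++halves;
      }
      u += t * step;
      h0 = joint(u, &g, &H);
      if (arma::norm(t * step) < 1e-9) break;
    }
    for (int j = 0; j < q; ++j) Uout(s, j) = u[j];

    // log |-H| via Cholesky of the (positive definite) negated Hessian
    arma::mat negH = -H;
    arma::mat C;
    if (!arma::chol(C, negH)) { ok = false; nll += 1e8; continue; }
    double logdet_negH = 2.0 * arma::sum(arma::log(C.diag()));
    // Laplace: log m_s = ll(u) - 0.5 logdet(Sigma) - 0.5 logdet(-H)
    nll -= h0 - 0.5 * logdet_Sigma - 0.5 * logdet_negH;
  }
  return List::create(_["nll"] = nll, _["U"] = Uout, _["ok"] = ok);
}

// Pooled (no random effect) negative log-likelihood and gradient; the
// sigma -> 0 limit, used for starting values and as a fast fallback.
// theta = (t1, g2, g3, beta).
// [[Rcpp::export]]
List cp_pooled_nll(NumericVector theta, IntegerVector y, NumericMatrix X) {
  const int p = X.ncol();
  const int n = X.nrow();
  double tau[3], e2, e3;
  unpack_tau(theta.begin(), tau, &e2, &e3);
  arma::vec beta(p);
  for (int j = 0; j < p; ++j) beta[j] = theta[3 + j];
  const arma::mat Xm(X.begin(), n, p, false);
  arma::vec eta0 = Xm * beta;
  double nll = 0.0;
  double dt1 = 0.0, dt2 = 0.0, dt3 = 0.0;
  arma::vec db(p, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    CellDeriv c = cell(eta0[i], y[i], tau, false);
    nll -= c.ll;
    dt1 -= c.dtau[0]; dt2 -= c.dtau[1]; dt3 -= c.dtau[2];
    for (int j = 0; j < p; ++j) db[j] -= c.d1 * Xm(i, j);
  }
  NumericVector grad(3 + p);
  grad[0] = dt1 + dt2 + dt3;
  grad[1] = e2 * (dt2 + dt3);
  grad[2] = e3 * dt3;
  for (int j = 0; j < p; ++j) grad[3 + j] = db[j];
  return List::create(_["nll"] = nll, _["grad"] = grad);
}
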