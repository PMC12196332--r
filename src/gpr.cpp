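// Dense derivative-observation GP solvers for the squared-exponential kernel.
//
// The gradient-gradient covariance is
//   Kgg(a, b) = (delta^2/theta^2) * (1 - (a-b)^2/theta^2) * exp(-(a-b)^2/(2 theta^2))
// and the regularized system (Kgg + diag(noise_var)) alpha = y is solved
// either by an in-place Cholesky factorization (moderate n) or, for large n,
// matrix-free by preconditioned conjugate gradients with a Nystrom
// (inducing-point) preconditioner, so the n x n matrix is never stored.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
# define FCONE
#endif
#include <cmath>
using namespace Rcpp;

static inline double kgg(double a, double b, double inv_t2, double amp) {
  const double d2 = (a - b) * (a - b);
  return amp * (1.0 - d2 * inv_t2) * std::exp(-0.5 * d2 * inv_t2);
}

// (Kgg + diag(noise_var)) %*% v, computed on the fly.
// [[Rcpp::export(name = ".cpp_kgg_matvec")]]
NumericVector cpp_kgg_matvec(NumericVector s, NumericVector v, double delta, double theta,
                             NumericVector noise_var) {
  const R_xlen_t n = s.size();
  const double inv_t2 = 1.0 / (theta * theta);
  const double amp = delta * delta * inv_t2;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (amp + noise_var[i]) * v[i];
  for (R_xlen_t i = 0; i < n; ++i) {
    const double si = s[i], vi = v[i];
    double acc = 0.0;
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double k = kgg(si, s[j], inv_t2, amp);
      acc += k * v[j];
      out[j] += k * vi;
    }
    out[i] += acc;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gpr_dense_chol")]]
List cpp_gpr_dense_chol(NumericVector s, NumericVector y, double delta, double theta,
                        NumericVector noise_var, NumericVector jitters, bool keep_factor) {
  const int n = (int)s.size();
  const double inv_t2 = 1.0 / (theta * theta);
  const double amp = delta * delta * inv_t2;
  NumericMatrix K(n, n);
  double jitter_used = NA_REAL;
  int info = -1;
  for (int attempt = 0; attempt <= jitters.size(); ++attempt) {
    const double jit = (attempt == 0) ? 0.0 : jitters[attempt - 1] * amp;
    for (int j = 0; j < n; ++j) {
      K(j, j) = amp + noise_var[j] + jit;
      for (int i = j + 1; i < n; ++i) {
        const double k = kgg(s[i], s[j], inv_t2, amp);
        K(i, j) = k;
        K(j, i) = k;
      }
    }
    F77_CALL(dpotrf)("L", &n, K.begin(), &n, &info FCONE);
    if (info == 0) { jitter_used = jit; break; }
  }
  if (info != 0)
    stop("Cholesky factorization failed even at the largest jitter (info = %d)", info);
  NumericVector alpha = clone(y);
  const int one = 1;
  F77_CALL(dpotrs)("L", &n, &one, K.begin(), &n, alpha.begin(), &n, &info FCONE);
  if (info != 0) stop("triangular solve failed (info = %d)", info);
  return List::create(_["alpha"] = alpha, _["jitter"] = jitter_used,
                      _["factor"] = keep_factor ? (SEXP)K : R_NilValue);
}

namespace {
// Woodbury application of the inverse Nystrom preconditioner
//   P = diag(lam) + B C^{-1} B^T  =>  P^{-1} r = r/lam - (B M^{-1} B^T (r/lam))/lam
// with M = C + B^T diag(1/lam) B (factorized once).
struct NystromPrecond {
  int n, m;
  std::vector<double> B;    // n x m, column major
  std::vector<double> M;    // m x m Cholesky factor
  std::vector<double> lam;  // noise variances

  void build(NumericVector s, NumericVector u, double inv_t2, double amp,
             NumericVector noise_var) {
    n = (int)s.size(); m = (int)u.size();
    lam.assign(noise_var.begin(), noise_var.end());
    B.assign((size_t)n * m, 0.0);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i)
        B[(size_t)j * n + i] = kgg(s[i], u[j], inv_t2, amp);
    std::vector<double> C((size_t)m * m);
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i)
        C[(size_t)j * m + i] = kgg(u[i], u[j], inv_t2, amp);
    // M = C + B^T diag(1/lam) B
    M.assign((size_t)m * m, 0.0);
    for (int j = 0; j < m; ++j)
      for (int i = j; i < m; ++i) {
        double acc = C[(size_t)j * m + i];
        const double *bi = &B[(size_t)i * n], *bj = &B[(size_t)j * n];
        for (int k = 0; k < n; ++k) acc += bi[k] * bj[k] / lam[k];
        M[(size_t)j * m + i] = acc;
        M[(size_t)i * m + j] = acc;
      }
    double tr = 0.0;
    for (int i = 0; i < m; ++i) tr += M[(size_t)i * m + i];
    int info = -1;
    double jit = 1e-12 * tr / m;
    std::vector<double> Mc;
    for (int attempt = 0; attempt < 12; ++attempt) {
      Mc = M;
      for (int i = 0; i < m; ++i) Mc[(size_t)i * m + i] += (attempt == 0 ? 0.0 : jit);
      F77_CALL(dpotrf)("L", &m, Mc.data(), &m, &info FCONE);
      if (info == 0) break;
      jit *= 100.0;
    }
    if (info != 0) Rcpp::stop("preconditioner factorization failed");
    M = Mc;
  }

  void apply(const std::vector<double> &r, std::vector<double> &z) const {
    std::vector<double> a(n), w(m, 0.0);
    for (int i = 0; i < n; ++i) a[i] = r[i] / lam[i];
    for (int j = 0; j < m; ++j) {
      const double *bj = &B[(size_t)j * n];
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += bj[i] * a[i];
      w[j] = acc;
    }
    int info = -1; const int one = 1;
    F77_CALL(dpotrs)("L", &m, &one, const_cast<double*>(M.data()), &m, w.data(), &m, &info FCONE);
    z = a;
    for (int j = 0; j < m; ++j) {
      const double *bj = &B[(size_t)j * n];
      const double wj = w[j];
      for (int i = 0; i < n; ++i) z[i] -= bj[i] * wj / lam[i];
    }
  }
};

void matvec(NumericVector s, const std::vector<double> &v, std::vector<double> &out,
            double inv_t2, double amp, const std::vector<double> &lam) {
  const R_xlen_t n = s.size();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (amp + lam[i]) * v[i];
  for (R_xlen_t i = 0; i < n; ++i) {
    const double si = s[i], vi = v[i];
    double acc = 0.0;
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double k = kgg(si, s[j], inv_t2, amp);
      acc += k * v[j];
      out[j] += k * vi;
    }
    out[i] += acc;
  }
}
} // namespace

// [[Rcpp::export(name = ".cpp_gpr_dense_pcg")]]
List cpp_gpr_dense_pcg(NumericVector s, NumericVector y, double delta, double theta,
                       NumericVector noise_var, NumericVector u, double tol, int maxit) {
  const R_xlen_t n = s.size();
  const double inv_t2 = 1.0 / (theta * theta);
  const double amp = delta * delta * inv_t2;
  NystromPrecond P;
  P.build(s, u, inv_t2, amp, noise_var);

  std::vector<double> x(n, 0.0), r(y.begin(), y.end()), z(n), p(n), q(n);
  double ynorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) ynorm += y[i] * y[i];
  ynorm = std::sqrt(ynorm);
  if (ynorm == 0.0)
    return List::create(_["alpha"] = NumericVector(n), _["iterations"] = 0, _["resid_rel"] = 0.0);

  P.apply(r, z);
  p = z;
  double rz = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) rz += r[i] * z[i];
  int it = 0;
  double rnorm = ynorm;
  for (it = 1; it <= maxit; ++it) {
    matvec(s, p, q, inv_t2, amp, P.lam);
    double pq = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pq += p[i] * q[i];
    const double a = rz / pq;
    for (R_xlen_t i = 0; i < n; ++i) { x[i] += a * p[i]; r[i] -= a * q[i]; }
    if (it % 50 == 0) { // refresh the true residual to cancel recursion drift
      matvec(s, x, q, inv_t2, amp, P.lam);
      for (R_xlen_t i = 0; i < n; ++i) r[i] = y[i] - q[i];
    }
    rnorm = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) rnorm += r[i] * r[i];
    rnorm = std::sqrt(rnorm);
    if (rnorm / ynorm < tol) break;
    P.apply(r, z);
    double rz_new = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) rz_new += r[i] * z[i];
    const double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    Rcpp::checkUserInterrupt();
  }
  // final true residual
  matvec(s, x, q, inv_t2, amp, P.lam);
  double res = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) { const double d = y[i] - q[i]; res += d * d; }
  return List::create(_["alpha"] = wrap(x), _["iterations"] = it,
                      _["resid_rel"] = std::sqrt(res) / ynorm);
}
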