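// FISTA core for the sampled joint Fourier-Laplace operator.
//
// The Fourier factor is applied through the FFT over the reconstruction
// grid: with f_k = -sw/2 + k*sw/nf and t1 = m/sw, the sampled synthesis
// row is (-1)^m exp(2*pi*i*m*k/nf)/nf, i.e. an (aliased) nf-point DFT
// with a per-sample sign and a row permutation between the package's
// frequency grid (bin nf is DC) and DFT bin order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// column-wise unnormalized FFT: precomputed-twiddle radix-2 when the
// length is a power of two (the usual reconstruction grid sizes),
// Armadillo's FFT otherwise.  dir = +1 gives sum exp(+2i pi ...)
// (unnormalized inverse), dir = -1 the forward transform.
struct FftPlan {
  int n;
  bool pow2;
  std::vector<unsigned> rev;                 // bit-reversal permutation
  std::vector<cx_double> twf, twi;           // per-stage twiddles, flat
  explicit FftPlan(int n_) : n(n_) {
    pow2 = n > 0 && (n & (n - 1)) == 0;
    if (!pow2 || n < 2) return;
    rev.resize(n);
    int lg = 0;
    while ((1 << lg) < n) ++lg;
    for (int i = 0; i < n; ++i) {
      unsigned r = 0;
      for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1u << (lg - 1 - b);
      rev[i] = r;
    }
    for (int len = 2; len <= n; len <<= 1)
      for (int k = 0; k < len / 2; ++k) {
        double ang = 2.0 * M_PI * k / len;
        twf.emplace_back(std::cos(ang), -std::sin(ang));
        twi.emplace_back(std::cos(ang), std::sin(ang));
      }
  }
  void run_col(cx_double* a, int dir) const {
    for (int i = 0; i < n; ++i)
      if ((unsigned)i < rev[i]) std::swap(a[i], a[rev[i]]);
    const cx_double* tw = (dir > 0 ? twi : twf).data();
    for (int len = 2; len <= n; len <<= 1) {
      const int half = len / 2;
      for (int i = 0; i < n; i += len)
        for (int k = 0; k < half; ++k) {
          const cx_double w = tw[k];
          cx_double u = a[i + k], v = a[i + k + half] * w;
          a[i + k] = u + v;
          a[i + k + half] = u - v;
        }
      tw += half;
    }
  }
  void run(cx_mat& X, int dir) const {
    if (pow2 && n >= 2) {
      for (uword j = 0; j < X.n_cols; ++j) run_col(X.colptr(j), dir);
    } else if (dir > 0) {
      X = ifft(X) * (double)n;
    } else {
      X = fft(X);
    }
  }
};

struct JointOp {
  cx_mat Lc;        // m x nr, Laplace factor (complex copy, sign folded in)
  uvec   row_idx;   // m, 0-based row of the t1 grid
  uword  nf, nr, m;
  mutable FftPlan plan;

  JointOp(const mat& Ls, const uvec& t1_mod, const vec& t1_sign, uword nf_)
    : Lc(Ls.n_rows, Ls.n_cols), row_idx(t1_mod - 1),
      nf(nf_), nr(Ls.n_cols), m(Ls.n_rows), plan((int)nf_) {
    for (uword j = 0; j < nr; ++j)
      for (uword i = 0; i < m; ++i)
        Lc(i, j) = cx_double(t1_sign(i) * Ls(i, j), 0.0);
  }

  // plane (nf x nr) -> samples (m)
  cx_vec forward(const cx_mat& Q) const {
    cx_mat V(nf, nr);
    V.row(0) = Q.row(nf - 1);
    if (nf > 1) V.rows(1, nf - 1) = Q.rows(0, nf - 2);
    plan.run(V, +1);                     // rows: nf * ifft convention
    const double sc = 1.0 / (double)nf;
    cx_vec s(m, fill::zeros);
    for (uword j = 0; j < nr; ++j) {
      const cx_double* vj = V.colptr(j);
      const cx_double* lj = Lc.colptr(j);
      for (uword i = 0; i < m; ++i)
        s(i) += vj[row_idx(i)] * lj[i];
    }
    return sc * s;
  }

  // samples (m) -> plane (nf x nr)
  cx_mat adjoint(const cx_vec& q) const {
    cx_mat U(nf, nr, fill::zeros);
    for (uword j = 0; j < nr; ++j) {
      cx_double* uj = U.colptr(j);
      const cx_double* lj = Lc.colptr(j);
      for (uword i = 0; i < m; ++i)
        uj[row_idx(i)] += q(i) * lj[i];
    }
    plan.run(U, -1);                     // rows: exp(-2i pi t k / nf)
    const double sc = 1.0 / (double)nf;
    cx_mat R(nf, nr);
    if (nf > 1) R.rows(0, nf - 2) = sc * U.rows(1, nf - 1);
    R.row(nf - 1) = sc * U.row(0);
    return R;
  }
};

void soft_mag_inplace(cx_mat& X, double theta) {
  if (theta <= 0.0) return;
  cx_double* p = X.memptr();
  const uword n = X.n_elem;
  for (uword i = 0; i < n; ++i) {
    double a = std::abs(p[i]);
    p[i] = (a > theta) ? p[i] * ((a - theta) / a) : cx_double(0.0, 0.0);
  }
}

double l1_norm(const cx_mat& X) {
  double s = 0.0;
  const cx_double* p = X.memptr();
  for (uword i = 0; i < X.n_elem; ++i) s += std::abs(p[i]);
  return s;
}

} // namespace

// [[Rcpp::export(name = ".fista_core")]]
Rcpp::List fista_core(const arma::mat& Ls, const arma::uvec& t1_mod,
                      const arma::vec& t1_sign, int nf,
                      const arma::cx_vec& q,
                      double tau, double theta0, int n_cont,
                      double step, int n_iter,
                      bool restart, bool monotone,
                      double tolerance, bool record_objective) {
  const JointOp op(Ls, t1_mod, t1_sign, (uword)nf);
  const uword nr = op.nr;
  cx_mat x((uword)nf, nr, fill::zeros), y = x;
  double tk = 1.0;
  const bool need_obj = record_objective || monotone || tolerance > 0;
  vec trace(need_obj ? n_iter : 0);
  double obj_prev = datum::inf, obj0 = datum::nan;
  int n_used = n_iter;
  const uword n_el = (uword)nf * nr;
  for (int it = 1; it <= n_iter; ++it) {
    double tau_it = (it <= n_cont && theta0 > tau)
      ? tau * std::pow(theta0 / tau, 1.0 - (it - 1.0) / n_cont) : tau;
    cx_vec r = op.forward(y) - q;
    cx_mat z = op.adjoint(r);          // becomes the prox point in place
    const double thr = step * tau_it;
    double c_restart = 0.0;
    {
      cx_double* zp = z.memptr();
      const cx_double* yp = y.memptr();
      const cx_double* xp = x.memptr();
      for (uword i = 0; i < n_el; ++i) {
        cx_double v = yp[i] - 2.0 * step * zp[i];   // gradient step
        double a = std::abs(v);
        v = (a > thr) ? v * ((a - thr) / a) : cx_double(0.0, 0.0);
        zp[i] = v;
        if (restart) {
          const cx_double d1 = yp[i] - v, d2 = v - xp[i];
          c_restart += d1.real() * d2.real() + d1.imag() * d2.imag();
        }
      }
    }
    double o_z = datum::nan;
    if (need_obj) {
      cx_vec rz = op.forward(z) - q;
      o_z = accu(square(abs(rz))) + tau * l1_norm(z);
    }
    bool keep_old = monotone && it > n_cont && o_z > obj_prev;
    double o_new = keep_old ? obj_prev : o_z;
    if (restart && c_restart > 0) tk = 1.0;
    double t_next = (1.0 + std::sqrt(1.0 + 4.0 * tk * tk)) / 2.0;
    if (keep_old) {                    // MFISTA: keep x, momentum along z
      y = x + (tk / t_next) * (z - x);
    } else {
      const double beta = (tk - 1.0) / t_next;
      cx_double* zp = z.memptr();
      cx_double* yp = y.memptr();
      cx_double* xp = x.memptr();
      for (uword i = 0; i < n_el; ++i) {
        const cx_double v = zp[i];
        yp[i] = v + beta * (v - xp[i]);
        xp[i] = v;
      }
    }
    tk = t_next;
    if (need_obj) trace(it - 1) = o_new;
    obj_prev = o_new;
    if (it == 1 && need_obj) obj0 = o_new;
    if (tolerance > 0 && it > n_cont + 1) {
      double prev = trace(it - 2);
      double rel = std::abs(trace(it - 1) - prev) /
        std::max(prev, datum::eps);
      if (rel < tolerance) { n_used = it; break; }
    }
  }
  bool diverged = false;
  if (need_obj && std::isfinite(obj0)) {
    for (int it = 0; it < n_used; ++it)
      if (trace(it) > 10.0 * obj0) { diverged = true; break; }
  }
  vec tr_out = need_obj ? vec(trace.head(n_used)) : vec();
  return Rcpp::List::create(Rcpp::Named("Q") = x,
                            Rcpp::Named("objective_trace") = tr_out,
                            Rcpp::Named("n_iter_used") = n_used,
                            Rcpp::Named("diverged") = diverged);
}
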