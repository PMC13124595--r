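// Direct-summation structure-factor kernel and its reverse-mode pull-back.
// Hot path of every likelihood evaluation: n_refl x n_atoms complex
// exponentials, so it lives in C++ with raw-pointer loops.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// F_h = sum_j occ_j f_hj exp(-B_j s2q_h) exp(2 pi i q_h . x_j)
// [[Rcpp::export(name = ".sf_kernel_forward")]]
List sf_kernel_forward(NumericMatrix q, NumericMatrix X, NumericMatrix fel,
                       NumericVector occ, NumericVector B, NumericVector s2q,
                       bool keep_terms) {
  const int n = q.nrow(), m = X.nrow();
  ComplexVector F(n);
  Rcomplex *Fp = F.begin();
  for (int h = 0; h < n; ++h) { Fp[h].r = 0.0; Fp[h].i = 0.0; }
  ComplexMatrix terms(keep_terms ? n : 1, keep_terms ? m : 1);
  Rcomplex *Tp = terms.begin();
  const double *qx = &q(0, 0), *qy = &q(0, 1), *qz = &q(0, 2);
  const double *Xp = &X(0, 0), *Yp = &X(0, 1), *Zp = &X(0, 2);
  const double *fp = fel.begin();
  const double *sp = s2q.begin();
  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < m; ++j) {
    const double xj = Xp[j], yj = Yp[j], zj = Zp[j];
    const double oj = occ[j], bj = B[j];
    const double *fj = fp + (size_t)j * n;
    Rcomplex *tj = keep_terms ? (Tp + (size_t)j * n) : 0;
    for (int h = 0; h < n; ++h) {
      const double amp = oj * fj[h] * std::exp(-bj * sp[h]);
      const double ph = twopi * (qx[h] * xj + qy[h] * yj + qz[h] * zj);
      const double tr = amp * std::cos(ph);
      const double ti = amp * std::sin(ph);
      Fp[h].r += tr;
      Fp[h].i += ti;
      if (tj) { tj[h].r = tr; tj[h].i = ti; }
    }
  }
  List out = List::create(Named("F") = F);
  if (keep_terms) out["terms"] = terms;
  return out;
}

// adjoint: dL/dx_{jc} = sum_h Re(conj(gF_h) * 2 pi i q_{hc} * terms_{hj})
//          dL/dB_j    = sum_h Re(conj(gF_h) * (-s2q_h) * terms_{hj})
// [[Rcpp::export(name = ".sf_kernel_backward")]]
List sf_kernel_backward(ComplexMatrix terms, NumericMatrix q,
                        NumericVector s2q, ComplexVector gF) {
  const int n = q.nrow(), m = terms.ncol();
  NumericMatrix dX(m, 3);
  NumericVector dB(m);
  const double *qx = &q(0, 0), *qy = &q(0, 1), *qz = &q(0, 2);
  const double *sp = s2q.begin();
  const Rcomplex *gp = gF.begin();
  const Rcomplex *Tp = terms.begin();
  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < m; ++j) {
    const Rcomplex *tj = Tp + (size_t)j * n;
    double d0 = 0.0, d1 = 0.0, d2 = 0.0, db = 0.0;
    for (int h = 0; h < n; ++h) {
      const double tr = tj[h].r, ti = tj[h].i;
      const double gr = gp[h].r, gi = gp[h].i;
      // Re(conj(g) * i * t) = gi*tr - gr*ti ; Re(conj(g) * t) = gr*tr + gi*ti
      const double w = twopi * (gi * tr - gr * ti);
      d0 += w * qx[h];
      d1 += w * qy[h];
      d2 += w * qz[h];
      db += -sp[h] * (gr * tr + gi * ti);
    }
    dX(j, 0) = d0; dX(j, 1) = d1; dX(j, 2) = d2;
    dB[j] = db;
  }
  return List::create(Named("dX") = dX, Named("dB") = dB);
}
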