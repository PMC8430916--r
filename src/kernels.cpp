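#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update on flat parameter/state vectors. The caller owns all
// four vectors (freshly allocated in the training loop, never shared), so
// in-place mutation is safe and avoids per-iteration GC churn.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector p, NumericVector m, NumericVector v,
                     NumericVector g, double lr, int t, double beta1,
                     double beta2, double eps) {
  const R_xlen_t n = p.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  const double a1 = 1.0 - beta1, a2 = 1.0 - beta2;
  const double invc2 = 1.0 / c2, lrc1 = lr / c1;
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v);
  const double *pg = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    pm[i] = beta1 * pm[i] + a1 * gi;
    pv[i] = beta2 * pv[i] + a2 * gi * gi;
    pp[i] -= lrc1 * pm[i] / (std::sqrt(pv[i] * invc2) + eps);
  }
}

// Z <- relu(Z + bias per column), in place.
// [[Rcpp::export]]
void add_bias_relu_cpp(NumericMatrix Z, NumericVector b) {
  const R_xlen_t n = Z.nrow(), k = Z.ncol();
  double *z = REAL(Z);
  const double *pb = REAL(b);
  for (R_xlen_t j = 0; j < k; ++j) {
    const double bj = pb[j];
    double *col = z + j * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double val = col[i] + bj;
      col[i] = val > 0 ? val : 0;
    }
  }
}

// A <- A * (act > 0), in place (relu gradient gate).
// [[Rcpp::export]]
void mul_relumask_cpp(NumericMatrix A, NumericMatrix act) {
  const R_xlen_t n = (R_xlen_t)A.nrow() * A.ncol();
  double *a = REAL(A);
  const double *m = REAL(act);
  for (R_xlen_t i = 0; i < n; ++i) if (m[i] <= 0) a[i] = 0;
}

// A <- A * rowmask (rowmask recycled down each column), in place.
// [[Rcpp::export]]
void mul_rowmask_cpp(NumericMatrix A, NumericVector mask) {
  const R_xlen_t n = A.nrow(), k = A.ncol();
  double *a = REAL(A);
  const double *m = REAL(mask);
  for (R_xlen_t j = 0; j < k; ++j) {
    double *col = a + j * n;
    for (R_xlen_t i = 0; i < n; ++i) if (m[i] == 0) col[i] = 0;
  }
}

// im2col for a 1D convolution over position-major activations: X is
// (n*L) x C with rows grouped by position (block l holds samples 1..n at
// position l); output is (n*L) x (kernel*C) with zero padding at borders.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix X, int n, int L, int kernel) {
  const int C = X.ncol();
  const int half = (kernel - 1) / 2;
  NumericMatrix out = no_init_matrix((R_xlen_t)n * L, (R_xlen_t)kernel * C);
  const double *x = REAL(X);
  double *o = REAL(out);
  const size_t nL = (size_t)n * L;
  for (int off = -half; off <= half; ++off) {
    const int bcol = (off + half) * C;
    for (int c = 0; c < C; ++c) {
      const double *src = x + (size_t)c * nL;
      double *dst = o + ((size_t)(bcol + c)) * nL;
      for (int l = 0; l < L; ++l) {
        const int sl = l + off;
        if (sl < 0 || sl >= L) {
          std::fill(dst + (size_t)l * n, dst + (size_t)(l + 1) * n, 0.0);
        } else {
          std::copy(src + (size_t)sl * n, src + (size_t)(sl + 1) * n,
                    dst + (size_t)l * n);
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add column blocks back to positions.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dXcol, int n, int L, int kernel,
                         int C) {
  const int half = (kernel - 1) / 2;
  NumericMatrix out((R_xlen_t)n * L, C);
  const double *x = REAL(dXcol);
  double *o = REAL(out);
  const size_t nL = (size_t)n * L;
  for (int off = -half; off <= half; ++off) {
    const int bcol = (off + half) * C;
    for (int c = 0; c < C; ++c) {
      const double *src = x + ((size_t)(bcol + c)) * nL;
      double *dst = o + (size_t)c * nL;
      for (int l = 0; l < L; ++l) {
        const int sl = l + off;
        if (sl < 0 || sl >= L) continue;
        const double *s = src + (size_t)l * n;
        double *d = dst + (size_t)sl * n;
        for (int i = 0; i < n; ++i) d[i] += s[i];
      }
    }
  }
  return out;
}

// Embedding gather: V[(l,i), ] = E[flat[(l,i)], ] with flat == 0 -> zeros.
// [[Rcpp::export]]
NumericMatrix embed_gather_cpp(NumericMatrix E, IntegerVector flat) {
  const int emb = E.ncol(), nA = E.nrow();
  const R_xlen_t n = flat.size();
  NumericMatrix out = no_init_matrix(n, emb);
  const double *e = REAL(E);
  double *o = REAL(out);
  const int *f = INTEGER(flat);
  for (int c = 0; c < emb; ++c) {
    const double *ec = e + (size_t)c * nA;
    double *oc = o + (size_t)c * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const int fi = f[i];
      oc[i] = fi > 0 ? ec[fi - 1] : 0.0;
    }
  }
  return out;
}

// Adjoint of the gather: accumulate dV rows into dE rows by token index.
// [[Rcpp::export]]
NumericMatrix embed_scatter_cpp(NumericMatrix dV, IntegerVector flat,
                                int n_alpha) {
  const int emb = dV.ncol();
  const R_xlen_t n = flat.size();
  NumericMatrix out(n_alpha, emb);
  const double *dv = REAL(dV);
  double *o = REAL(out);
  const int *f = INTEGER(flat);
  for (int c = 0; c < emb; ++c) {
    const double *sc = dv + (size_t)c * n;
    double *oc = o + (size_t)c * n_alpha;
    for (R_xlen_t i = 0; i < n; ++i) {
      const int fi = f[i];
      if (fi > 0) oc[fi - 1] += sc[i];
    }
  }
  return out;
}

// Stride-2 max pooling over position-major blocks: input (n*2*L2) x C,
// output (n*L2) x C plus the winner indicator (1 if the first position of
// the pair won).
// [[Rcpp::export]]
List maxpool2_cpp(NumericMatrix A, int n, int L2) {
  const int C = A.ncol();
  NumericMatrix out = no_init_matrix((R_xlen_t)n * L2, C);
  NumericMatrix sel = no_init_matrix((R_xlen_t)n * L2, C);
  const double *a = REAL(A);
  double *o = REAL(out), *s = REAL(sel);
  const size_t nL = (size_t)n * 2 * L2, nP = (size_t)n * L2;
  for (int c = 0; c < C; ++c) {
    const double *ac = a + (size_t)c * nL;
    double *oc = o + (size_t)c * nP, *sc = s + (size_t)c * nP;
    for (int l = 0; l < L2; ++l) {
      const double *p1 = ac + (size_t)(2 * l) * n;
      const double *p2 = p1 + n;
      double *op = oc + (size_t)l * n, *sp = sc + (size_t)l * n;
      for (int i = 0; i < n; ++i) {
        if (p1[i] >= p2[i]) { op[i] = p1[i]; sp[i] = 1.0; }
        else { op[i] = p2[i]; sp[i] = 0.0; }
      }
    }
  }
  return List::create(_["out"] = out, _["sel"] = sel);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bwd_cpp(NumericMatrix dOut, NumericMatrix sel,
                               int n, int L2) {
  const int C = dOut.ncol();
  NumericMatrix dA = no_init_matrix((R_xlen_t)n * 2 * L2, C);
  const double *d = REAL(dOut), *s = REAL(sel);
  double *o = REAL(dA);
  const size_t nL = (size_t)n * 2 * L2, nP = (size_t)n * L2;
  for (int c = 0; c < C; ++c) {
    const double *dc = d + (size_t)c * nP, *sc = s + (size_t)c * nP;
    double *oc = o + (size_t)c * nL;
    for (int l = 0; l < L2; ++l) {
      const double *dp = dc + (size_t)l * n, *sp = sc + (size_t)l * n;
      double *o1 = oc + (size_t)(2 * l) * n;
      double *o2 = o1 + n;
      for (int i = 0; i < n; ++i) {
        const double d0 = dp[i];
        if (sp[i] != 0) { o1[i] = d0; o2[i] = 0.0; }
        else { o1[i] = 0.0; o2[i] = d0; }
      }
    }
  }
  return dA;
}

// Global max + mean pooling over positions with padding-aware lengths:
// A is (n*L2) x C position-major, mask is the n*L2 validity vector.
// Returns max matrix M, mean matrix S, argmax positions (1-based) and the
// per-sample valid length.
// [[Rcpp::export]]
List global_pool_cpp(NumericMatrix A, NumericVector mask, int n, int L2) {
  const int C = A.ncol();
  NumericMatrix M = no_init_matrix(n, C), S = no_init_matrix(n, C);
  IntegerMatrix amax = no_init_matrix(n, C);
  NumericVector len = no_init(n);
  const double *a = REAL(A), *mk = REAL(mask);
  double *pm = REAL(M), *ps = REAL(S), *plen = REAL(len);
  int *pa = INTEGER(amax);
  for (int i = 0; i < n; ++i) {
    double cnt = 0;
    for (int l = 0; l < L2; ++l) cnt += mk[(size_t)l * n + i] != 0 ? 1 : 0;
    plen[i] = cnt > 0 ? cnt : 1;
  }
  const size_t nP = (size_t)n * L2;
  for (int c = 0; c < C; ++c) {
    const double *ac = a + (size_t)c * nP;
    double *mc = pm + (size_t)c * n, *sc = ps + (size_t)c * n;
    int *axc = pa + (size_t)c * n;
    for (int i = 0; i < n; ++i) { mc[i] = ac[i]; axc[i] = 1; sc[i] = ac[i]; }
    for (int l = 1; l < L2; ++l) {
      const double *bl = ac + (size_t)l * n;
      for (int i = 0; i < n; ++i) {
        sc[i] += bl[i];
        if (bl[i] > mc[i]) { mc[i] = bl[i]; axc[i] = l + 1; }
      }
    }
    for (int i = 0; i < n; ++i) sc[i] /= plen[i];
  }
  return List::create(_["M"] = M, _["S"] = S, _["amax"] = amax,
                      _["len"] = len);
}

// [[Rcpp::export]]
NumericMatrix global_pool_bwd_cpp(NumericMatrix dM, NumericMatrix dS,
                                  IntegerMatrix amax, NumericVector len,
                                  int n, int L2) {
  const int C = dM.ncol();
  NumericMatrix dA = no_init_matrix((R_xlen_t)n * L2, C);
  const double *pdm = REAL(dM), *pds = REAL(dS), *plen = REAL(len);
  const int *pa = INTEGER(amax);
  double *o = REAL(dA);
  const size_t nP = (size_t)n * L2;
  for (int c = 0; c < C; ++c) {
    const double *dmc = pdm + (size_t)c * n, *dsc = pds + (size_t)c * n;
    const int *axc = pa + (size_t)c * n;
    double *oc = o + (size_t)c * nP;
    for (int l = 0; l < L2; ++l) {
      double *op = oc + (size_t)l * n;
      for (int i = 0; i < n; ++i) op[i] = dsc[i] / plen[i];
    }
    for (int i = 0; i < n; ++i) {
      oc[(size_t)(axc[i] - 1) * n + i] += dmc[i];
    }
  }
  return dA;
}
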