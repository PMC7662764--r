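// Hot inner kernels of the ST-GCN forward/backward passes.
//
// Activations are stored as (C, T, N, V) arrays — channel-major with the
// node axis last — so the spatial aggregation is a single BLAS product on
// the (C*T*N, V) matricization (done in R).  The kernels below implement
// the per-channel temporal convolution and the fused batch-norm + ReLU.
// They use plain Rcpp views (no copy of the inputs): these operations are
// memory-bandwidth bound, so avoiding temporaries is what matters.

#include <Rcpp.h>
using namespace Rcpp;

// Fused unit forward: depthwise temporal convolution -> batch norm -> ReLU
// in two passes over the conv input, without materializing the convolution
// output.  H: (C, T, S); in training mode batch statistics are computed in
// the first pass, otherwise the supplied running statistics are used.
// `out_dim` is the dim attribute to stamp on the activation (same linear
// layout).  Returns out, xhat (training only), mu, var, istd.
// [[Rcpp::export]]
List unit_fwd_cpp(NumericVector H, NumericMatrix w, NumericVector b,
                  NumericVector gamma, NumericVector beta,
                  NumericVector mu0, NumericVector var0, bool train,
                  double eps, IntegerVector out_dim) {
  IntegerVector hd = H.attr("dim");
  const int C = hd[0], T = hd[1], S = hd[2], K = w.ncol();
  const int hw = (K - 1) / 2;
  const R_xlen_t M = (R_xlen_t)T * S;
  const double* h = H.begin();
  const double* wp = w.begin();
  std::vector<double> z(C);
  NumericVector mu(C), va(C);
  auto conv_col = [&](int s, int t) {
    const R_xlen_t off_s = (R_xlen_t)s * C * T;
    for (int i = 0; i < C; ++i) z[i] = b[i];
    for (int k = 0; k < K; ++k) {
      const int ts = t + k - hw;
      if (ts < 0 || ts >= T) continue;
      const double* hc = h + off_s + (R_xlen_t)ts * C;
      const double* wk = wp + (R_xlen_t)k * C;
      for (int i = 0; i < C; ++i) z[i] += wk[i] * hc[i];
    }
  };
  if (train) {
    for (int s = 0; s < S; ++s)
      for (int t = 0; t < T; ++t) {
        conv_col(s, t);
        for (int i = 0; i < C; ++i) {
          mu[i] += z[i];
          va[i] += z[i] * z[i];
        }
      }
    for (int i = 0; i < C; ++i) {
      mu[i] /= (double)M;
      va[i] = va[i] / (double)M - mu[i] * mu[i];
    }
  } else {
    mu = mu0;
    va = var0;
  }
  NumericVector istd(C);
  for (int i = 0; i < C; ++i) istd[i] = 1.0 / std::sqrt(va[i] + eps);
  NumericVector out((R_xlen_t)C * M);
  out.attr("dim") = out_dim;
  double* o = out.begin();
  NumericMatrix xhat(train ? C : 0, train ? M : 0);
  double* xp = xhat.begin();
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t) {
      conv_col(s, t);
      const R_xlen_t off = ((R_xlen_t)s * T + t) * C;
      for (int i = 0; i < C; ++i) {
        const double v = (z[i] - mu[i]) * istd[i];
        if (train) xp[off + i] = v;
        const double y = gamma[i] * v + beta[i];
        o[off + i] = y > 0 ? y : 0.0;
      }
    }
  return List::create(Named("out") = out,
                      Named("xhat") = train ? (SEXP)xhat : R_NilValue,
                      Named("mu") = mu, Named("var") = va,
                      Named("istd") = istd);
}

// Fully fused unit backward: ReLU mask -> batch-norm gradient -> depthwise
// temporal-convolution backward in two passes, without materializing the
// intermediate batch-norm gradient for the caller.
// dOut/out/xhat: (C, T*S) matrices; istd/gamma: per-channel vectors;
// H: (C, T, S) temporal-conv input; w: (C, K) kernel.
// Returns dH (gradient w.r.t. H), dw, db (temporal conv), dgamma, dbeta.
// [[Rcpp::export]]
List unit_bwd_cpp(NumericVector dOut, NumericVector out, NumericMatrix xhat,
                  NumericVector istd, NumericVector gamma,
                  NumericVector H, NumericMatrix w) {
  IntegerVector hd = H.attr("dim");
  const int C = hd[0], T = hd[1], S = hd[2], K = w.ncol();
  const int hw = (K - 1) / 2;
  const R_xlen_t M = (R_xlen_t)T * S;
  NumericVector dg(C), db_bn(C), m1(C), m2(C);
  NumericMatrix dxhat(C, M);
  const double* dop = dOut.begin();
  const double* op = out.begin();
  const double* xh = xhat.begin();
  double* dxp = dxhat.begin();
  // pass 1: ReLU mask, BN reductions, store dxhat
  for (R_xlen_t j = 0; j < M; ++j) {
    const R_xlen_t off = j * C;
    for (int i = 0; i < C; ++i) {
      const double dy = op[off + i] > 0 ? dop[off + i] : 0.0;
      dg[i] += dy * xh[off + i];
      db_bn[i] += dy;
      const double d = dy * gamma[i];
      dxp[off + i] = d;
      m1[i] += d;
      m2[i] += d * xh[off + i];
    }
  }
  for (int i = 0; i < C; ++i) {
    m1[i] /= (double)M;
    m2[i] /= (double)M;
  }
  // pass 2: finish dZ per column and consume it in the temporal-conv
  // backward immediately (dZ columns are local in (t, s))
  NumericVector dH(H.size());
  dH.attr("dim") = IntegerVector::create(C, (int)M);   // consumed as (C, M)
  NumericMatrix dw(C, K);
  NumericVector db_t(C);
  const double* h = H.begin();
  const double* wp = w.begin();
  double* dh = dH.begin();
  double* dwp = dw.begin();
  std::vector<double> dz(C);
  for (int s = 0; s < S; ++s) {
    const R_xlen_t off_s = (R_xlen_t)s * C * T;
    for (int t = 0; t < T; ++t) {
      const R_xlen_t off = off_s + (R_xlen_t)t * C;
      for (int i = 0; i < C; ++i)
        dz[i] = istd[i] * (dxp[off + i] - m1[i] - xh[off + i] * m2[i]);
      for (int i = 0; i < C; ++i) db_t[i] += dz[i];
      for (int k = 0; k < K; ++k) {
        const int ts = t + k - hw;
        if (ts < 0 || ts >= T) continue;
        const R_xlen_t off_ts = off_s + (R_xlen_t)ts * C;
        const double* wk = wp + (R_xlen_t)k * C;
        double* dwk = dwp + (R_xlen_t)k * C;
        for (int i = 0; i < C; ++i) {
          dh[off_ts + i] += wk[i] * dz[i];
          dwk[i] += dz[i] * h[off_ts + i];
        }
      }
    }
  }
  return List::create(Named("dH") = dH, Named("dw") = dw,
                      Named("db") = db_t, Named("dgamma") = dg,
                      Named("dbeta") = db_bn);
}

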