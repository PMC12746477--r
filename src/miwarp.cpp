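// Parzen soft-binned mutual information (value + gradient w.r.t. the
// second image) and the trilinear warp with its spatial gradient — the
// per-step hot path of registration training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// normalised Gaussian soft-assignment weights (n x bins)
static mat parzen(const vec& v, int bins, double sigma) {
  mat G(v.n_elem, bins);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int b = 0; b < bins; ++b) {
    const double c = (b + 0.5) / bins;
    for (uword i = 0; i < v.n_elem; ++i) {
      const double d = v[i] - c;
      G(i, b) = std::exp(-d * d * inv2s2);
    }
  }
  const vec s = sum(G, 1);
  G.each_col() /= s;
  return G;
}

// [[Rcpp::export]]
Rcpp::List mi_soft_cpp(const arma::vec& fn, const arma::vec& wn, int bins,
                       double sigma, bool want_grad) {
  const double eps = 1e-10;
  const double n = fn.n_elem;
  mat A = parzen(fn, bins, sigma);
  mat B = parzen(wn, bins, sigma);
  mat P = (A.t() * B) / n;
  vec pf = sum(P, 1);
  rowvec pw = sum(P, 0);
  mat lp = log(P + eps);
  lp.each_col() -= log(pf + eps);
  lp.each_row() -= log(pw + eps);
  const double mi = accu(P % lp);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("mi") = std::max(mi, 0.0),
      Rcpp::Named("joint") = P);
  if (want_grad) {
    mat Gp = lp - 1.0;            // dMI/dP
    mat D = (A * Gp) / n;         // n x bins, dMI/dB
    vec g(fn.n_elem);
    const double inv_s2 = 1.0 / (sigma * sigma);
    for (uword i = 0; i < wn.n_elem; ++i) {
      double mu = 0.0;
      for (int b = 0; b < bins; ++b)
        mu += B(i, b) * ((b + 0.5) / bins - wn[i]) * inv_s2;
      double acc = 0.0;
      for (int b = 0; b < bins; ++b)
        acc += D(i, b) * B(i, b) * (((b + 0.5) / bins - wn[i]) * inv_s2 - mu);
      g[i] = acc;
    }
    out["dmi_dw"] = g;
  }
  return out;
}

// trilinear warp w(x) = m(x + u(x)) with border clamping; optionally the
// spatial gradient of the sampled value w.r.t. the displacement vector
// [[Rcpp::export]]
Rcpp::List warp_grad_cpp(const arma::vec& m, const arma::ivec& dims,
                         const arma::mat& u, bool want_grad) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const long long n = (long long)d0 * d1 * d2;
  Rcpp::NumericVector wr(n);
  Rcpp::NumericMatrix gr(want_grad ? n : 1, want_grad ? 3 : 1);
  long long idx = 0;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i, ++idx) {
        double c0 = i + u(idx, 0), c1 = j + u(idx, 1), c2 = k + u(idx, 2);
        const bool in0 = c0 > 0.0 && c0 < d0 - 1.0;
        const bool in1 = c1 > 0.0 && c1 < d1 - 1.0;
        const bool in2 = c2 > 0.0 && c2 < d2 - 1.0;
        c0 = std::min(std::max(c0, 0.0), (double)(d0 - 1));
        c1 = std::min(std::max(c1, 0.0), (double)(d1 - 1));
        c2 = std::min(std::max(c2, 0.0), (double)(d2 - 1));
        int f0 = std::min((int)c0, d0 - 2); if (d0 == 1) f0 = 0;
        int f1 = std::min((int)c1, d1 - 2); if (d1 == 1) f1 = 0;
        int f2 = std::min((int)c2, d2 - 2); if (d2 == 1) f2 = 0;
        const double t0 = c0 - f0, t1 = c1 - f1, t2 = c2 - f2;
        const int o0 = d0 > 1 ? 1 : 0;
        const long long s1 = d0, s2 = (long long)d0 * d1;
        const int o1 = d1 > 1 ? 1 : 0, o2 = d2 > 1 ? 1 : 0;
        const long long base = f0 + (long long)f1 * s1 + (long long)f2 * s2;
        const double v000 = m[base],            v100 = m[base + o0];
        const double v010 = m[base + o1 * s1],  v110 = m[base + o0 + o1 * s1];
        const double v001 = m[base + o2 * s2],  v101 = m[base + o0 + o2 * s2];
        const double v011 = m[base + o1 * s1 + o2 * s2];
        const double v111 = m[base + o0 + o1 * s1 + o2 * s2];
        const double w00 = v000 * (1 - t0) + v100 * t0;
        const double w10 = v010 * (1 - t0) + v110 * t0;
        const double w01 = v001 * (1 - t0) + v101 * t0;
        const double w11 = v011 * (1 - t0) + v111 * t0;
        const double w0 = w00 * (1 - t1) + w10 * t1;
        const double w1 = w01 * (1 - t1) + w11 * t1;
        wr[idx] = w0 * (1 - t2) + w1 * t2;
        if (want_grad) {
          const double g00 = v100 - v000, g10 = v110 - v010;
          const double g01 = v101 - v001, g11 = v111 - v011;
          gr(idx, 0) = in0 ? ((g00 * (1 - t1) + g10 * t1) * (1 - t2) +
                              (g01 * (1 - t1) + g11 * t1) * t2) : 0.0;
          gr(idx, 1) = in1 ? ((w10 - w00) * (1 - t2) + (w11 - w01) * t2) : 0.0;
          gr(idx, 2) = in2 ? (w1 - w0) : 0.0;
        }
      }
  return Rcpp::List::create(Rcpp::Named("value") = wr,
                            Rcpp::Named("grad") = gr);
}
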