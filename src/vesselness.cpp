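// Frangi tube-likelihood from Hessian components: per voxel, eigenvalues of
// the symmetric 3x3 Hessian sorted by magnitude |l1| <= |l2| <= |l3|, then
//   V = (1 - exp(-Ra^2/2a^2)) * exp(-Rb^2/2b^2) * (1 - exp(-S^2/2c^2))
// with Ra = |l2|/|l3|, Rb = |l1|/sqrt(|l2 l3|), S = sqrt(sum l_i^2).
// Bright tubes require l2, l3 < 0; dark tubes (vessels here) l2, l3 > 0.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector frangi_from_hessian_cpp(NumericVector hzz, NumericVector hyy,
                                      NumericVector hxx, NumericVector hzy,
                                      NumericVector hzx, NumericVector hyx,
                                      double alpha, double beta, double c,
                                      bool dark) {
  size_t V = hzz.size();
  NumericVector out(V);
  arma::mat33 Hm;
  arma::vec3 ev;
  double a2 = 2.0 * alpha * alpha, b2 = 2.0 * beta * beta, c2 = 2.0 * c * c;
  for (size_t v = 0; v < V; ++v) {
    Hm(0, 0) = hzz[v]; Hm(1, 1) = hyy[v]; Hm(2, 2) = hxx[v];
    Hm(0, 1) = Hm(1, 0) = hzy[v];
    Hm(0, 2) = Hm(2, 0) = hzx[v];
    Hm(1, 2) = Hm(2, 1) = hyx[v];
    arma::eig_sym(ev, Hm);
    // sort by absolute value
    double l[3] = {ev[0], ev[1], ev[2]};
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2 - i; ++j)
        if (std::abs(l[j]) > std::abs(l[j + 1])) std::swap(l[j], l[j + 1]);
    double l2 = l[1], l3 = l[2];
    bool sign_ok = dark ? (l2 > 0 && l3 > 0) : (l2 < 0 && l3 < 0);
    if (!sign_ok || l3 == 0.0) continue;
    double Ra = std::abs(l2) / std::abs(l3);
    double Rb = std::abs(l[0]) / std::sqrt(std::abs(l2 * l3));
    double S2 = l[0] * l[0] + l2 * l2 + l3 * l3;
    double resp = (1.0 - std::exp(-Ra * Ra / a2)) *
                  std::exp(-Rb * Rb / b2);
    if (c2 > 0) resp *= 1.0 - std::exp(-S2 / c2);
    out[v] = resp;
  }
  return out;
}
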