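#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

//' 3D bilateral filter (Gaussian spatial x Gaussian range weights).
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_bilateral3d(NumericVector data, IntegerVector dims,
                              double sigma_s, double sigma_r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = std::max(1, (int)std::ceil(2.0 * sigma_s));
  // precompute spatial weights
  const int side = 2 * h + 1;
  std::vector<double> ws(side * side * side);
  for (int c = -h; c <= h; ++c)
    for (int b = -h; b <= h; ++b)
      for (int a = -h; a <= h; ++a)
        ws[(a + h) + side * ((b + h) + side * (c + h))] =
            std::exp(-0.5 * (a * a + b * b + c * c) / (sigma_s * sigma_s));
  const double inv2r2 = 0.5 / (sigma_r * sigma_r);
  NumericVector out(data.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double v0 = data[idx], num = 0.0, den = 0.0;
        for (int c = std::max(-h, -k); c <= std::min(h, nz - 1 - k); ++c)
          for (int b = std::max(-h, -j); b <= std::min(h, ny - 1 - j); ++b)
            for (int a = std::max(-h, -i); a <= std::min(h, nx - 1 - i); ++a) {
              R_xlen_t q = idx + a + (R_xlen_t)nx * (b + (R_xlen_t)ny * c);
              double dv = data[q] - v0;
              double w = ws[(a + h) + side * ((b + h) + side * (c + h))] *
                         std::exp(-dv * dv * inv2r2);
              num += w * data[q];
              den += w;
            }
        out[idx] = num / den;
      }
  return out;
}
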