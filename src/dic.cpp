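#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local (window) DIC: integer-voxel normalised cross-correlation search
// followed by sub-voxel refinement using trilinear-interpolated
// least squares on the intensity residual (translation only).

namespace {

inline double trilinear(const NumericVector& v, int nx, int ny, int nz,
                        double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  // caller guarantees in-bounds with one-voxel margin
  R_xlen_t b = i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double c00 = v[b] * (1 - fx) + v[b + sx] * fx;
  double c10 = v[b + sy] * (1 - fx) + v[b + sy + sx] * fx;
  double c01 = v[b + sz] * (1 - fx) + v[b + sz + sx] * fx;
  double c11 = v[b + sz + sy] * (1 - fx) + v[b + sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_dic(NumericVector ref, NumericVector def, IntegerVector dims,
                      IntegerMatrix centers, int half, int search,
                      double var_floor, double ncc_floor, int max_iter,
                      double tol) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = centers.nrow();
  const int side = 2 * half + 1;
  const int wn = side * side * side;
  NumericMatrix out(n, 5); // ux uy uz ncc status
  std::vector<double> rb(wn), db(wn);

  // central-difference gradient volumes of def (for refinement)
  R_xlen_t nvox = def.size();
  std::vector<double> gx(nvox, 0.0), gy(nvox, 0.0), gz(nvox, 0.0);
  R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        R_xlen_t p = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        gx[p] = 0.5 * (def[p + 1] - def[p - 1]);
        gy[p] = 0.5 * (def[p + nx] - def[p - nx]);
        gz[p] = 0.5 * (def[p + sz] - def[p - sz]);
      }

  for (int w = 0; w < n; ++w) {
    int cx = centers(w, 0), cy = centers(w, 1), cz = centers(w, 2);
    // bounds: ref window, and def window over the whole search range + margin
    int m = search + 2;
    if (cx - half < 0 || cx + half >= nx || cy - half < 0 || cy + half >= ny ||
        cz - half < 0 || cz + half >= nz || cx - half - m < 0 ||
        cx + half + m >= nx || cy - half - m < 0 || cy + half + m >= ny ||
        cz - half - m < 0 || cz + half + m >= nz) {
      out(w, 4) = 1; // out_of_bounds
      continue;
    }
    // ref block
    double rsum = 0, rsum2 = 0;
    int t = 0;
    for (int c = -half; c <= half; ++c)
      for (int b = -half; b <= half; ++b)
        for (int a = -half; a <= half; ++a, ++t) {
          double v = ref[(cx + a) + (R_xlen_t)nx *
                                        ((cy + b) + (R_xlen_t)ny * (cz + c))];
          rb[t] = v;
          rsum += v;
          rsum2 += v * v;
        }
    double rmean = rsum / wn;
    double rvar = rsum2 / wn - rmean * rmean;
    if (rvar < var_floor) {
      out(w, 4) = 2; // featureless window
      continue;
    }
    double rnorm = std::sqrt(rvar * wn);
    // integer NCC search
    double best = -2.0;
    int bi = 0, bj = 0, bk = 0;
    for (int skk = -search; skk <= search; ++skk)
      for (int sjj = -search; sjj <= search; ++sjj)
        for (int sii = -search; sii <= search; ++sii) {
          double dsum = 0, dsum2 = 0, cross = 0;
          t = 0;
          for (int c = -half; c <= half; ++c)
            for (int b = -half; b <= half; ++b) {
              R_xlen_t base = (cx + sii - half) +
                              (R_xlen_t)nx * ((cy + sjj + b) +
                                              (R_xlen_t)ny * (cz + skk + c));
              for (int a = 0; a < side; ++a, ++t) {
                double v = def[base + a];
                dsum += v;
                dsum2 += v * v;
                cross += v * rb[t];
              }
            }
          double dmean = dsum / wn;
          double dvar = dsum2 / wn - dmean * dmean;
          if (dvar <= 0) continue;
          double ncc = (cross - wn * rmean * dmean) /
                       (rnorm * std::sqrt(dvar * wn));
          if (ncc > best) {
            best = ncc;
            bi = sii; bj = sjj; bk = skk;
          }
        }
    if (best < ncc_floor) {
      out(w, 4) = 2;
      continue;
    }
    // sub-voxel refinement: minimise sum (def(x+u) - ref(x) - offset)^2
    double ux = bi, uy = bj, uz = bk;
    NumericVector defv = def;
    for (int it = 0; it < max_iter; ++it) {
      double A[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      double rhs[3] = {0, 0, 0};
      double res_sum = 0;
      int cnt = 0;
      // first pass: mean residual (grey-offset compensation)
      for (int c = -half; c <= half; ++c)
        for (int b = -half; b <= half; ++b)
          for (int a = -half; a <= half; ++a) {
            double x = cx + a + ux, y = cy + b + uy, z = cz + c + uz;
            double g = trilinear(defv, nx, ny, nz, x, y, z);
            double r0 = rb[(a + half) + side * ((b + half) + side * (c + half))];
            res_sum += g - r0;
            ++cnt;
          }
      double offset = res_sum / cnt;
      for (int c = -half; c <= half; ++c)
        for (int b = -half; b <= half; ++b)
          for (int a = -half; a <= half; ++a) {
            double x = cx + a + ux, y = cy + b + uy, z = cz + c + uz;
            double g = trilinear(defv, nx, ny, nz, x, y, z);
            double r0 = rb[(a + half) + side * ((b + half) + side * (c + half))];
            double e = r0 - (g - offset);
            // interpolated image gradient at the sample position
            double ggx = 0, ggy = 0, ggz = 0;
            {
              int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
                  k0 = (int)std::floor(z);
              double fx = x - i0, fy = y - j0, fz = z - k0;
              R_xlen_t bb = i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
              R_xlen_t sy = nx;
              double wgt[8] = {(1 - fx) * (1 - fy) * (1 - fz),
                               fx * (1 - fy) * (1 - fz),
                               (1 - fx) * fy * (1 - fz),
                               fx * fy * (1 - fz),
                               (1 - fx) * (1 - fy) * fz,
                               fx * (1 - fy) * fz,
                               (1 - fx) * fy * fz,
                               fx * fy * fz};
              R_xlen_t off[8] = {0, 1, sy, sy + 1, sz, sz + 1, sz + sy,
                                 sz + sy + 1};
              for (int q = 0; q < 8; ++q) {
                ggx += wgt[q] * gx[bb + off[q]];
                ggy += wgt[q] * gy[bb + off[q]];
                ggz += wgt[q] * gz[bb + off[q]];
              }
            }
            A[0] += ggx * ggx; A[1] += ggx * ggy; A[2] += ggx * ggz;
            A[4] += ggy * ggy; A[5] += ggy * ggz; A[8] += ggz * ggz;
            rhs[0] += ggx * e; rhs[1] += ggy * e; rhs[2] += ggz * e;
          }
      A[3] = A[1]; A[6] = A[2]; A[7] = A[5];
      // solve 3x3 system (Cramer)
      double det = A[0] * (A[4] * A[8] - A[5] * A[7]) -
                   A[1] * (A[3] * A[8] - A[5] * A[6]) +
                   A[2] * (A[3] * A[7] - A[4] * A[6]);
      if (std::fabs(det) < 1e-12) break;
      double dux = (rhs[0] * (A[4] * A[8] - A[5] * A[7]) -
                    A[1] * (rhs[1] * A[8] - A[5] * rhs[2]) +
                    A[2] * (rhs[1] * A[7] - A[4] * rhs[2])) / det;
      double duy = (A[0] * (rhs[1] * A[8] - A[5] * rhs[2]) -
                    rhs[0] * (A[3] * A[8] - A[5] * A[6]) +
                    A[2] * (A[3] * rhs[2] - rhs[1] * A[6])) / det;
      double duz = (A[0] * (A[4] * rhs[2] - rhs[1] * A[7]) -
                    A[1] * (A[3] * rhs[2] - rhs[1] * A[6]) +
                    rhs[0] * (A[3] * A[7] - A[4] * A[6])) / det;
      ux += dux; uy += duy; uz += duz;
      if (std::sqrt(dux * dux + duy * duy + duz * duz) < tol) break;
    }
    // guard against refinement drifting away from the correlation peak
    if (std::fabs(ux - bi) > 1.5 || std::fabs(uy - bj) > 1.5 ||
        std::fabs(uz - bk) > 1.5) {
      ux = bi; uy = bj; uz = bk;
    }
    out(w, 0) = ux; out(w, 1) = uy; out(w, 2) = uz;
    out(w, 3) = best;
    out(w, 4) = 0;
  }
  return out;
}
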