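#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topological thinning of a 3D binary mask to a one-voxel-wide curve
// skeleton: directional border peeling with a simple-point test
// (Bertrand & Malandain characterisation) and endpoint preservation.

namespace {

// local 3x3x3 neighbourhood copy, centre at (1,1,1)
inline int lidx(int a, int b, int c) { return a + 3 * (b + 3 * c); }

// number of 26-connected components of object voxels in N26(p) \ {p}
int count_object_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int pa = p % 3, pb = (p / 3) % 3, pc = p / 9;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int qa = pa + a, qb = pb + b, qc = pc + c;
            if (qa < 0 || qa > 2 || qb < 0 || qb > 2 || qc < 0 || qc > 2)
              continue;
            int q = lidx(qa, qb, qc);
            if (q == 13 || q == p || seen[q] || !nb[q]) continue;
            seen[q] = true;
            stack.push_back(q);
          }
    }
  }
  return comps;
}

// number of 6-connected components of background voxels in N18(p) that
// are 6-adjacent to p
int count_background_components(const bool nb[27]) {
  // N18: offsets with at most two non-zero coordinates
  bool in18[27];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int c = 0; c < 3; ++c) {
        int nz = (a != 1) + (b != 1) + (c != 1);
        in18[lidx(a, b, c)] = (nz >= 1 && nz <= 2);
      }
  static const int six[6] = {lidx(0, 1, 1), lidx(2, 1, 1), lidx(1, 0, 1),
                             lidx(1, 2, 1), lidx(1, 1, 0), lidx(1, 1, 2)};
  bool seen[27] = {false};
  int comps = 0;
  for (int t = 0; t < 6; ++t) {
    int s = six[t];
    if (nb[s] || seen[s]) continue; // need background seed 6-adjacent to p
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int pa = p % 3, pb = (p / 3) % 3, pc = p / 9;
      const int da[6] = {-1, 1, 0, 0, 0, 0};
      const int db[6] = {0, 0, -1, 1, 0, 0};
      const int dc[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int qa = pa + da[m], qb = pb + db[m], qc = pc + dc[m];
        if (qa < 0 || qa > 2 || qb < 0 || qb > 2 || qc < 0 || qc > 2) continue;
        int q = lidx(qa, qb, qc);
        if (q == 13 || !in18[q] || nb[q] || seen[q]) continue;
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  return comps;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;
  const int dirx[6] = {-1, 1, 0, 0, 0, 0};
  const int diry[6] = {0, 0, -1, 1, 0, 0};
  const int dirz[6] = {0, 0, 0, 0, -1, 1};

  auto at = [&](int i, int j, int k) -> char {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0;
    return m[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  auto fill_nb = [&](int i, int j, int k, bool nb[27]) {
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a)
          nb[lidx(a + 1, b + 1, c + 1)] = at(i + a, j + b, k + c) != 0;
  };
  auto n26_count = [&](int i, int j, int k) {
    int n = 0;
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          if (a == 0 && b == 0 && c == 0) continue;
          n += at(i + a, j + b, k + c) != 0;
        }
    return n;
  };

  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            if (!m[idx]) continue;
            if (at(i + dirx[d], j + diry[d], k + dirz[d])) continue; // not a d-border voxel
            cand.push_back(idx);
          }
      for (R_xlen_t t = 0; t < (R_xlen_t)cand.size(); ++t) {
        R_xlen_t idx = cand[t];
        if (!m[idx]) continue;
        int i = idx % nx, j = (idx / nx) % ny, k = idx / ((R_xlen_t)nx * ny);
        int nnb = n26_count(i, j, k);
        if (nnb <= 1) continue; // endpoint (or isolated): keep
        bool nb[27];
        fill_nb(i, j, k, nb);
        if (count_object_components(nb) != 1) continue;
        if (count_background_components(nb) != 1) continue;
        m[idx] = 0; // simple point: delete (sequential within subiteration)
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  return out;
}
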