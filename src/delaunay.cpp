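#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson 3D Delaunay tetrahedralisation.
// Intended for point sets of a few thousand (grain centres, DIC grids with
// jitter applied by the caller for degenerate/cospherical configurations).

namespace {

struct Tet {
  int v[4];
  double cc[3]; // circumcentre
  double r2;    // squared circumradius
  bool alive;
};

// circumsphere of 4 points; returns false if (near) degenerate
bool circumsphere(const double* p0, const double* p1, const double* p2,
                  const double* p3, double* cc, double& r2) {
  double A[9], b[3];
  for (int r = 0; r < 3; ++r) {
    const double* pr = (r == 0) ? p1 : (r == 1) ? p2 : p3;
    double rhs = 0;
    for (int c = 0; c < 3; ++c) {
      A[3 * r + c] = 2.0 * (pr[c] - p0[c]);
      rhs += pr[c] * pr[c] - p0[c] * p0[c];
    }
    b[r] = rhs;
  }
  double det = A[0] * (A[4] * A[8] - A[5] * A[7]) -
               A[1] * (A[3] * A[8] - A[5] * A[6]) +
               A[2] * (A[3] * A[7] - A[4] * A[6]);
  if (std::fabs(det) < 1e-14) return false;
  cc[0] = (b[0] * (A[4] * A[8] - A[5] * A[7]) -
           A[1] * (b[1] * A[8] - A[5] * b[2]) +
           A[2] * (b[1] * A[7] - A[4] * b[2])) / det;
  cc[1] = (A[0] * (b[1] * A[8] - A[5] * b[2]) -
           b[0] * (A[3] * A[8] - A[5] * A[6]) +
           A[2] * (A[3] * b[2] - b[1] * A[6])) / det;
  cc[2] = (A[0] * (A[4] * b[2] - b[1] * A[7]) -
           A[1] * (A[3] * b[2] - b[1] * A[6]) +
           b[0] * (A[3] * A[7] - A[4] * A[6])) / det;
  double dx = cc[0] - p0[0], dy = cc[1] - p0[1], dz = cc[2] - p0[2];
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay3d(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return IntegerMatrix(0, 4);
  // normalise into [0,1]^3
  std::vector<double> P((n + 4) * 3);
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = hi[c] = pts(0, c);
    for (int i = 1; i < n; ++i) {
      lo[c] = std::min(lo[c], pts(i, c));
      hi[c] = std::max(hi[c], pts(i, c));
    }
  }
  double scale = std::max(1e-12, std::max(hi[0] - lo[0],
                          std::max(hi[1] - lo[1], hi[2] - lo[2])));
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) P[3 * i + c] = (pts(i, c) - lo[c]) / scale;
  // super-tetrahedron
  const double S = 100.0;
  double sup[4][3] = {{-S, -S, -S}, {S, 0.5, 0.5}, {0.5, S, 0.5}, {0.5, 0.5, S}};
  for (int s = 0; s < 4; ++s)
    for (int c = 0; c < 3; ++c) P[3 * (n + s) + c] = sup[s][c];

  std::vector<Tet> tets;
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    circumsphere(&P[3 * t0.v[0]], &P[3 * t0.v[1]], &P[3 * t0.v[2]],
                 &P[3 * t0.v[3]], t0.cc, t0.r2);
    t0.alive = true;
    tets.push_back(t0);
  }

  const double eps = 1e-10;
  for (int ip = 0; ip < n; ++ip) {
    const double* p = &P[3 * ip];
    // cavity: all live tets whose circumsphere contains p
    std::vector<int> cavity;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double dx = p[0] - tets[t].cc[0], dy = p[1] - tets[t].cc[1],
             dz = p[2] - tets[t].cc[2];
      if (dx * dx + dy * dy + dz * dz < tets[t].r2 + eps)
        cavity.push_back((int)t);
    }
    if (cavity.empty()) continue; // should not happen inside super-tet
    // boundary faces = faces occurring exactly once in the cavity
    std::map<std::vector<int>, std::vector<int> > faces; // sorted face -> verts
    for (size_t q = 0; q < cavity.size(); ++q) {
      Tet& T = tets[cavity[q]];
      T.alive = false;
      static const int fid[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
      for (int f = 0; f < 4; ++f) {
        std::vector<int> key(3);
        key[0] = T.v[fid[f][0]]; key[1] = T.v[fid[f][1]]; key[2] = T.v[fid[f][2]];
        std::sort(key.begin(), key.end());
        std::map<std::vector<int>, std::vector<int> >::iterator it =
            faces.find(key);
        if (it == faces.end())
          faces[key] = key;
        else
          faces.erase(it); // internal face, seen twice
      }
    }
    for (std::map<std::vector<int>, std::vector<int> >::iterator it =
             faces.begin();
         it != faces.end(); ++it) {
      Tet nt;
      nt.v[0] = it->second[0]; nt.v[1] = it->second[1];
      nt.v[2] = it->second[2]; nt.v[3] = ip;
      if (!circumsphere(&P[3 * nt.v[0]], &P[3 * nt.v[1]], &P[3 * nt.v[2]],
                        &P[3 * nt.v[3]], nt.cc, nt.r2))
        continue; // degenerate sliver against the cavity wall: skip
      nt.alive = true;
      tets.push_back(nt);
    }
  }
  // collect tets not touching the super vertices
  int m = 0;
  for (size_t t = 0; t < tets.size(); ++t)
    if (tets[t].alive && tets[t].v[0] < n && tets[t].v[1] < n &&
        tets[t].v[2] < n && tets[t].v[3] < n)
      ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!(tets[t].alive && tets[t].v[0] < n && tets[t].v[1] < n &&
          tets[t].v[2] < n && tets[t].v[3] < n))
      continue;
    for (int c = 0; c < 4; ++c) out(r, c) = tets[t].v[c] + 1; // 1-based
    ++r;
  }
  return out;
}
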