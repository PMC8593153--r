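#include <Rcpp.h>
#include <vector>
#include <queue>
#include <tuple>
using namespace Rcpp;

// neighbour offsets for 6- or 26-connectivity
static void neighbour_offsets(int conn, std::vector<int>& dx,
                              std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && m > 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbour_offsets(conn, dx, dy, dz);
  const int nn = (int)dx.size();
  IntegerVector lab(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx] || lab[idx] != 0) continue;
        ++cur;
        lab[idx] = cur;
        stack.push_back(idx);
        while (!stack.empty()) {
          R_xlen_t p = stack.back();
          stack.pop_back();
          int pi = p % nx, pj = (p / nx) % ny, pk = p / ((R_xlen_t)nx * ny);
          for (int m = 0; m < nn; ++m) {
            int qi = pi + dx[m], qj = pj + dy[m], qk = pk + dz[m];
            if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 || qk >= nz)
              continue;
            R_xlen_t q = qi + (R_xlen_t)nx * (qj + (R_xlen_t)ny * qk);
            if (mask[q] && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
        }
      }
  return lab;
}

//' Marker-based watershed by priority flooding (ascending priority).
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector markers,
                              LogicalVector mask, IntegerVector dims,
                              int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbour_offsets(conn, dx, dy, dz);
  const int nn = (int)dx.size();
  IntegerVector lab(markers.size());
  for (R_xlen_t i = 0; i < markers.size(); ++i) lab[i] = markers[i];
  typedef std::tuple<double, long long, R_xlen_t> Node; // (prio, order, idx)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < markers.size(); ++i)
    if (markers[i] > 0 && mask[i]) pq.push(Node(priority[i], order++, i));
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    R_xlen_t p = std::get<2>(nd);
    int pi = p % nx, pj = (p / nx) % ny, pk = p / ((R_xlen_t)nx * ny);
    for (int m = 0; m < nn; ++m) {
      int qi = pi + dx[m], qj = pj + dy[m], qk = pk + dz[m];
      if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 || qk >= nz)
        continue;
      R_xlen_t q = qi + (R_xlen_t)nx * (qj + (R_xlen_t)ny * qk);
      if (!mask[q] || lab[q] != 0) continue;
      lab[q] = lab[p];
      pq.push(Node(priority[q], order++, q));
    }
  }
  return lab;
}
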