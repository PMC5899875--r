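#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Directed mean nearest-neighbour distance between two point sets (mm),
// brute force; point counts here are boundary voxels of desk-scale masks.
// [[Rcpp::export]]
double directed_mean_nn_cpp(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double total = 0;
  for (int i = 0; i < na; i++) {
    double best = R_PosInf;
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; j++) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / na;
}

// 26-connected component labelling of a logical 3D array (BFS).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector shape) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector labels(N, 0);
  const int *m = LOGICAL(mask);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < N; s++) {
    if (!m[s] || labels[s]) continue;
    cur++;
    stack.clear();
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; dz++) {
        int z2 = z + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; dy++) {
          int y2 = y + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; dx++) {
            int x2 = x + dx;
            if (x2 < 0 || x2 >= nx) continue;
            size_t w = x2 + (size_t)y2 * nx + (size_t)z2 * nx * ny;
            if (m[w] && !labels[w]) {
              labels[w] = cur;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = shape;
  return labels;
}
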