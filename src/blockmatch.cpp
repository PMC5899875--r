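#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive block matching with |NCC| similarity.
//
// Blocks are tiled over the reference at stride = block - overlap; only the
// top `keep_frac` by reference-block intensity variance are searched. For
// each kept block an exhaustive integer-shift search within +-half maximises
// the absolute Pearson correlation against the moving volume. Ties are
// broken by smallest displacement magnitude, then lexicographic (dz,dy,dx)
// order, making results deterministic. Shifted blocks that leave the moving
// volume are skipped.
//
// Returns a matrix with one row per matched block:
// (bx,by,bz block start voxel, dx,dy,dz shift in voxels, |ncc|, variance).

// [[Rcpp::export]]
NumericMatrix block_match_cpp(NumericVector ref, NumericVector mov,
                              IntegerVector shape, int block, int half,
                              int stride, double keep_frac) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  const double *rf = ref.begin(), *mv = mov.begin();
  size_t sy = nx, sz = (size_t)nx * ny;
  int nb = block * block * block;
  struct Blk { int x, y, z; double var, mean; };
  std::vector<Blk> blocks;
  for (int z = 0; z + block <= nz; z += stride)
    for (int y = 0; y + block <= ny; y += stride)
      for (int x = 0; x + block <= nx; x += stride) {
        double s = 0, s2 = 0;
        bool has_na = false;
        for (int k = 0; k < block && !has_na; k++)
          for (int j = 0; j < block; j++) {
            const double *p = rf + (x) + (size_t)(y + j) * sy + (size_t)(z + k) * sz;
            for (int i = 0; i < block; i++) {
              double v = p[i];
              if (ISNAN(v)) { has_na = true; break; }
              s += v; s2 += v * v;
            }
            if (has_na) break;
          }
        if (has_na) continue;
        double mean = s / nb;
        double var = s2 / nb - mean * mean;
        if (var > 1e-12) {
          Blk b; b.x = x; b.y = y; b.z = z; b.var = var; b.mean = mean;
          blocks.push_back(b);
        }
      }
  if (blocks.empty()) return NumericMatrix(0, 8);
  // variance filter: keep the top fraction
  std::vector<double> vars(blocks.size());
  for (size_t i = 0; i < blocks.size(); i++) vars[i] = blocks[i].var;
  std::sort(vars.begin(), vars.end());
  size_t nkeep = (size_t)std::ceil(keep_frac * blocks.size());
  if (nkeep < 1) nkeep = 1;
  double thresh = vars[blocks.size() - nkeep];
  std::vector<std::vector<double> > rows;
  for (size_t bi = 0; bi < blocks.size(); bi++) {
    const Blk &b = blocks[bi];
    if (b.var < thresh) continue;
    // precompute centered reference block
    std::vector<double> rb(nb);
    int idx = 0;
    for (int k = 0; k < block; k++)
      for (int j = 0; j < block; j++) {
        const double *p = rf + b.x + (size_t)(b.y + j) * sy + (size_t)(b.z + k) * sz;
        for (int i = 0; i < block; i++) rb[idx++] = p[i] - b.mean;
      }
    double rnorm2 = 0;
    for (int i = 0; i < nb; i++) rnorm2 += rb[i] * rb[i];
    double best = -1.0;
    int bdx = 0, bdy = 0, bdz = 0;
    bool found = false;
    for (int dz = -half; dz <= half; dz++) {
      int z0 = b.z + dz;
      if (z0 < 0 || z0 + block > nz) continue;
      for (int dy = -half; dy <= half; dy++) {
        int y0 = b.y + dy;
        if (y0 < 0 || y0 + block > ny) continue;
        for (int dx = -half; dx <= half; dx++) {
          int x0 = b.x + dx;
          if (x0 < 0 || x0 + block > nx) continue;
          double s = 0, s2 = 0, sp = 0;
          bool has_na = false;
          int ii = 0;
          for (int k = 0; k < block && !has_na; k++)
            for (int j = 0; j < block; j++) {
              const double *p = mv + x0 + (size_t)(y0 + j) * sy + (size_t)(z0 + k) * sz;
              for (int i = 0; i < block; i++) {
                double v = p[i];
                if (ISNAN(v)) { has_na = true; break; }
                s += v; s2 += v * v; sp += v * rb[ii++];
              }
              if (has_na) break;
            }
          if (has_na) continue;
          double mvar = s2 - s * s / nb;
          if (mvar <= 1e-12) continue;
          // sp already uses centered ref, so subtracting ref-mean cross term
          // is unnecessary: sum(rb) = 0
          double ncc = std::fabs(sp) / std::sqrt(rnorm2 * mvar);
          double better = ncc - best;
          bool take = false;
          if (better > 1e-12) take = true;
          else if (better > -1e-12) {
            int m2new = dx * dx + dy * dy + dz * dz;
            int m2old = bdx * bdx + bdy * bdy + bdz * bdz;
            if (m2new < m2old) take = true;
            else if (m2new == m2old &&
                     (dz < bdz || (dz == bdz && (dy < bdy || (dy == bdy && dx < bdx)))))
              take = true;
          }
          if (take) { best = ncc; bdx = dx; bdy = dy; bdz = dz; found = true; }
        }
      }
    }
    if (!found) continue;
    std::vector<double> row(8);
    row[0] = b.x; row[1] = b.y; row[2] = b.z;
    row[3] = bdx; row[4] = bdy; row[5] = bdz;
    row[6] = best; row[7] = b.var;
    rows.push_back(row);
  }
  NumericMatrix out(rows.size(), 8);
  for (size_t i = 0; i < rows.size(); i++)
    for (int j = 0; j < 8; j++) out(i, j) = rows[i][j];
  return out;
}
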