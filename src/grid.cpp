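// Grid helpers for the pocket finder: per-voxel burial counting along
// precomputed ray offsets.

#include <Rcpp.h>
using namespace Rcpp;

// For each empty voxel, count how many ray directions hit the
// solvent-excluded region.  `offsets` has one row per (direction, step)
// sample: column 0 is the direction id (1-based, ascending), columns 1-3
// the integer voxel offsets.
// [[Rcpp::export(name = ".burial_counts_cpp")]]
IntegerVector burial_counts_cpp(const LogicalVector& excluded,
                                const IntegerVector& dims,
                                const IntegerVector& empty_idx,
                                const IntegerMatrix& offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = empty_idx.size(), m = offsets.nrow();
  IntegerVector out(n);
  for (int v = 0; v < n; ++v) {
    const int lin = empty_idx[v] - 1;
    const int i = lin % nx;
    const int j = (lin / nx) % ny;
    const int k = lin / (nx * ny);
    int hits = 0, cur_dir = -1;
    bool dir_hit = false;
    for (int r = 0; r < m; ++r) {
      const int d = offsets(r, 0);
      if (d != cur_dir) {
        if (dir_hit) ++hits;
        cur_dir = d;
        dir_hit = false;
      }
      if (dir_hit) continue;
      const int i2 = i + offsets(r, 1);
      if (i2 < 0 || i2 >= nx) continue;
      const int j2 = j + offsets(r, 2);
      if (j2 < 0 || j2 >= ny) continue;
      const int k2 = k + offsets(r, 3);
      if (k2 < 0 || k2 >= nz) continue;
      if (excluded[i2 + nx * j2 + nx * ny * k2]) dir_hit = true;
    }
    if (dir_hit) ++hits;
    out[v] = hits;
  }
  return out;
}
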