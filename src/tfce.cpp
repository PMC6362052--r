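#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path compression + union by size.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement of a non-negative 3D map.
//
// TFCE(v) = sum over thresholds h = dh, 2dh, ... <= max of
//           extent(v, h)^E * h^H * dh,
// where extent(v, h) is the size of the connected component containing v
// among voxels >= h, under 6- or 26-connectivity. Implemented by sweeping
// thresholds from high to low with an incremental union-find: at each level
// the newly supra-threshold voxels are merged into components, then every
// active voxel accumulates size^E * h^H * dh.
//
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    if (map[i] < 0) stop("tfce_cpp expects a non-negative map");
    if (map[i] > mx) mx = map[i];
  }
  if (mx <= 0.0 || dh <= 0.0) return out;

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  // voxels sorted by height, descending
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (map[i] > 0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return map[a] > map[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // number of threshold levels h = dh, 2dh, ... <= max (with a relative
  // tolerance so an exactly-commensurate max keeps its top level)
  const int nlev = (int)std::floor(mx / dh + 1e-7);
  std::size_t next = 0;
  std::vector<int> activated;  // activation order, for the accumulation pass
  activated.reserve(order.size());

  for (int lev = nlev; lev >= 1; --lev) {
    const double h = lev * dh;
    // activate voxels with map >= h and merge with active neighbours
    while (next < order.size() && map[order[next]] >= h) {
      const int v = order[next++];
      active[v] = 1;
      csize[v] = 1;
      activated.push_back(v);
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (std::size_t k = 0; k < dxs.size(); ++k) {
        const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int w = xx + nx * (yy + ny * zz);
        if (!active[w]) continue;
        int ra = uf_find(parent, v), rb = uf_find(parent, w);
        if (ra == rb) continue;
        if (csize[ra] < csize[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        csize[ra] += csize[rb];
      }
    }
    // accumulate this level's contribution for every active voxel
    const double hH = std::pow(h, H) * dh;
    for (std::size_t k = 0; k < activated.size(); ++k) {
      const int v = activated[k];
      const int r = uf_find(parent, v);
      out[v] += std::pow((double)csize[r], E) * hH;
    }
  }
  return out;
}
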