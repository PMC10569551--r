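// Seeded 3D region growing: breadth-first growth from all voxels with
// prob >= s through neighbours with prob >= t, under 6- or 26-connectivity.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector region_grow_cpp(NumericVector prob, IntegerVector dims,
                              double s, double t, int connectivity) {
  int D = dims[0], H = dims[1], W = dims[2];
  size_t V = (size_t)D * H * W;
  IntegerVector out(V);
  std::vector<int> queue;
  queue.reserve(1024);
  const double* p = REAL(prob);
  for (size_t v = 0; v < V; ++v)
    if (p[v] >= s) { out[v] = 1; queue.push_back((int)v); }

  std::vector<std::array<int,3>> nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        nb.push_back({dz, dy, dx});
      }

  size_t head = 0;
  while (head < queue.size()) {
    int v = queue[head++];
    int z = v % D, y = (v / D) % H, x = v / (D * H);
    for (const auto& d : nb) {
      int nz = z + d[0], ny = y + d[1], nx = x + d[2];
      if (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      int u = nz + D * (ny + H * nx);
      if (!out[u] && p[u] >= t) { out[u] = 1; queue.push_back(u); }
    }
  }
  out.attr("dim") = dims;
  return out;
}
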