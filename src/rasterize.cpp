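// Rasterise tube segments: a voxel is foreground when its centre lies within
// the segment radius of any centreline segment (Euclidean point-to-segment
// distance). Coordinates are 0-based continuous voxel units in (z, y, x).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector rasterize_segments_cpp(IntegerVector dims, NumericMatrix segs) {
  int D = dims[0], H = dims[1], W = dims[2];
  IntegerVector out((size_t)D * H * W);
  for (int i = 0; i < segs.nrow(); ++i) {
    double az = segs(i, 0), ay = segs(i, 1), ax = segs(i, 2);
    double bz = segs(i, 3), by = segs(i, 4), bx = segs(i, 5);
    double r = segs(i, 6);
    double r2 = r * r;
    int z0 = std::max(0, (int)std::floor(std::min(az, bz) - r));
    int z1 = std::min(D - 1, (int)std::ceil(std::max(az, bz) + r));
    int y0 = std::max(0, (int)std::floor(std::min(ay, by) - r));
    int y1 = std::min(H - 1, (int)std::ceil(std::max(ay, by) + r));
    int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - r));
    int x1 = std::min(W - 1, (int)std::ceil(std::max(ax, bx) + r));
    double uz = bz - az, uy = by - ay, ux = bx - ax;
    double len2 = uz * uz + uy * uy + ux * ux;
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double pz = z - az, py = y - ay, px = x - ax;
          double tt = 0.0;
          if (len2 > 0) {
            tt = (pz * uz + py * uy + px * ux) / len2;
            tt = std::max(0.0, std::min(1.0, tt));
          }
          double dz = pz - tt * uz, dy = py - tt * uy, dx = px - tt * ux;
          if (dz * dz + dy * dy + dx * dx <= r2)
            out[z + (size_t)D * (y + (size_t)H * x)] = 1;
        }
  }
  out.attr("dim") = dims;
  return out;
}
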