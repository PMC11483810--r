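#include <Rcpp.h>
using namespace Rcpp;

// Rasterise tubular segments onto a voxel grid. A voxel belongs to the mask
// iff its centre lies within the segment radius of the segment axis
// (physical distance); intensity ramps linearly from 1 at the axis-distance
// radius down to 0 one voxel (max spacing) further out.
// segments: n x 7 matrix (x0,y0,z0,x1,y1,z1,radius), physical um.
// [[Rcpp::export(name = ".rasterize_cpp")]]
List rasterize_cpp(NumericMatrix segments, IntegerVector dim,
                   NumericVector origin, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector vol(V);
  IntegerVector mask(V);
  double h = std::max(spacing[0], std::max(spacing[1], spacing[2]));

  for (int s = 0; s < segments.nrow(); ++s) {
    double ax = segments(s, 0), ay = segments(s, 1), az = segments(s, 2);
    double bx = segments(s, 3), by = segments(s, 4), bz = segments(s, 5);
    double r = segments(s, 6);
    double reach = r + h;
    double lo[3], hi[3];
    lo[0] = std::min(ax, bx) - reach; hi[0] = std::max(ax, bx) + reach;
    lo[1] = std::min(ay, by) - reach; hi[1] = std::max(ay, by) + reach;
    lo[2] = std::min(az, bz) - reach; hi[2] = std::max(az, bz) + reach;
    int i0 = std::max(0, (int)std::ceil((lo[0] - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((hi[0] - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((lo[1] - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((hi[1] - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::ceil((lo[2] - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor((hi[2] - origin[2]) / spacing[2]));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + k * spacing[2];
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + j * spacing[1];
        for (int i = i0; i <= i1; ++i) {
          double px = origin[0] + i * spacing[0];
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = L2 > 0 ? (wx * ux + wy * uy + wz * uz) / L2 : 0.0;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          if (d <= r) mask[idx] = 1;
          double val = (r + h - d) / h;
          if (val > 1.0) val = 1.0;
          if (val > vol[idx]) vol[idx] = val;
        }
      }
    }
  }
  vol.attr("dim") = dim;
  mask.attr("dim") = dim;
  return List::create(_["volume"] = vol, _["mask"] = mask);
}
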