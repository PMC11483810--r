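#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Nearest-neighbour queries between 3D point clouds via a uniform cell hash
// (cell edge = max_dist, 27-cell probe). Returns for each query point the
// 1-based index of the nearest reference point within max_dist (0 if none)
// and the distance (NA if none).

static inline long long cell_key(long long ix, long long iy, long long iz) {
  // pack shifted cell coordinates into one 64-bit key (21 bits per axis)
  return ((ix + 1048576LL) << 42) | ((iy + 1048576LL) << 21) | (iz + 1048576LL);
}

// [[Rcpp::export(name = ".nn_search_cpp")]]
List nn_search_cpp(NumericMatrix ref, NumericMatrix query, double max_dist) {
  int n = ref.nrow(), m = query.nrow();
  double cell = max_dist > 0 ? max_dist : 1.0;
  std::unordered_map<long long, std::vector<int> > hash;
  hash.reserve(n * 2);
  for (int t = 0; t < n; ++t) {
    long long ix = (long long)std::floor(ref(t, 0) / cell);
    long long iy = (long long)std::floor(ref(t, 1) / cell);
    long long iz = (long long)std::floor(ref(t, 2) / cell);
    hash[cell_key(ix, iy, iz)].push_back(t);
  }
  IntegerVector idx(m);
  NumericVector dist(m);
  double md2 = max_dist * max_dist;
  for (int q = 0; q < m; ++q) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    long long ix = (long long)std::floor(qx / cell);
    long long iy = (long long)std::floor(qy / cell);
    long long iz = (long long)std::floor(qz / cell);
    int best = -1; double bd2 = md2;
    for (long long dz = -1; dz <= 1; ++dz)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dx = -1; dx <= 1; ++dx) {
          auto it = hash.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == hash.end()) continue;
          for (int t : it->second) {
            double ddx = ref(t, 0) - qx, ddy = ref(t, 1) - qy, ddz = ref(t, 2) - qz;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= bd2) { bd2 = d2; best = t; }
          }
        }
    idx[q] = best + 1;
    dist[q] = best >= 0 ? std::sqrt(bd2) : NA_REAL;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
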