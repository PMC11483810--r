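#include <Rcpp.h>
using namespace Rcpp;

// Fused metric evaluation for the affine optimiser: pulls the moving volume
// through the candidate transform onto the evaluation grid and accumulates
// NCC sufficient statistics or the MI joint histogram in one pass, without
// materialising the warped volume.

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double ci, double cj, double ck) {
  int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj), k0 = (int)std::floor(ck);
  double fi = ci - i0, fj = cj - j0, fk = ck - k0;
  if (i0 >= 0 && j0 >= 0 && k0 >= 0 && i0 < nx - 1 && j0 < ny - 1 && k0 < nz - 1) {
    const double* p = v + i0 + (size_t)nx * (j0 + (size_t)ny * k0);
    size_t sy = nx, sz = (size_t)nx * ny;
    double c00 = p[0] * (1 - fi) + p[1] * fi;
    double c10 = p[sy] * (1 - fi) + p[sy + 1] * fi;
    double c01 = p[sz] * (1 - fi) + p[sz + 1] * fi;
    double c11 = p[sz + sy] * (1 - fi) + p[sz + sy + 1] * fi;
    return (c00 * (1 - fj) + c10 * fj) * (1 - fk) +
           (c01 * (1 - fj) + c11 * fj) * fk;
  }
  if (ci < -0.5 || cj < -0.5 || ck < -0.5 ||
      ci > nx - 0.5 || cj > ny - 0.5 || ck > nz - 0.5) return 0.0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk; if (k < 0 || k >= nz) continue;
    double wk = dk ? fk : 1.0 - fk;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj; if (j < 0 || j >= ny) continue;
      double wj = dj ? fj : 1.0 - fj;
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di; if (i < 0 || i >= nx) continue;
        double wi = di ? fi : 1.0 - fi;
        acc += wi * wj * wk * v[i + (size_t)nx * (j + (size_t)ny * k)];
      }
    }
  }
  return acc;
}

// kind 0: NCC. kind 1: MI with `bins` bins; f_bins are precomputed 1-based
// bin indices of the fixed image on the evaluation grid.
// [[Rcpp::export(name = ".metric_affine_cpp")]]
double metric_affine_cpp(NumericVector fvals, IntegerVector f_bins,
                         NumericVector gvals, IntegerVector dim_g,
                         NumericVector origin_g, NumericVector spacing_g,
                         IntegerVector dim_e, NumericVector origin_e,
                         NumericVector spacing_e, NumericMatrix T,
                         int kind, int bins, double g_lo, double g_hi) {
  int nx = dim_g[0], ny = dim_g[1], nz = dim_g[2];
  int mx = dim_e[0], my = dim_e[1], mz = dim_e[2];
  const double* gv = gvals.begin();
  const double* fv = fvals.begin();
  size_t V = (size_t)mx * my * mz;
  double t00 = T(0,0), t01 = T(0,1), t02 = T(0,2), t03 = T(0,3);
  double t10 = T(1,0), t11 = T(1,1), t12 = T(1,2), t13 = T(1,3);
  double t20 = T(2,0), t21 = T(2,1), t22 = T(2,2), t23 = T(2,3);

  std::vector<double> w(kind == 0 ? 0 : V);
  size_t idx = 0;
  double sf = 0, sw = 0, sff = 0, sww = 0, sfw = 0;
  for (int k = 0; k < mz; ++k) {
    double pz = origin_e[2] + k * spacing_e[2];
    for (int j = 0; j < my; ++j) {
      double py = origin_e[1] + j * spacing_e[1];
      for (int i = 0; i < mx; ++i, ++idx) {
        double px = origin_e[0] + i * spacing_e[0];
        double qx = t00 * px + t01 * py + t02 * pz + t03;
        double qy = t10 * px + t11 * py + t12 * pz + t13;
        double qz = t20 * px + t21 * py + t22 * pz + t23;
        double val = trilinear(gv, nx, ny, nz,
                               (qx - origin_g[0]) / spacing_g[0],
                               (qy - origin_g[1]) / spacing_g[1],
                               (qz - origin_g[2]) / spacing_g[2]);
        if (kind == 0) {
          double f = fv[idx];
          sf += f; sw += val; sff += f * f; sww += val * val; sfw += f * val;
        } else w[idx] = val;
      }
    }
  }
  if (kind == 0) {
    double n = (double)V;
    double cov = sfw - sf * sw / n;
    double vf = sff - sf * sf / n;
    double vw = sww - sw * sw / n;
    if (vf <= 0 || vw <= 0) return -1.0;
    return cov / std::sqrt(vf * vw);
  }
  // MI: joint histogram; g binned over a fixed precomputed range so bin
  // edges do not shift with the candidate transform
  std::vector<double> joint((size_t)bins * bins, 0.0);
  double range = g_hi - g_lo;
  for (size_t t = 0; t < V; ++t) {
    int gb;
    if (range <= 0) gb = 0;
    else {
      gb = (int)((w[t] - g_lo) / range * bins);
      if (gb >= bins) gb = bins - 1;
      if (gb < 0) gb = 0;
    }
    joint[(size_t)(f_bins[t] - 1) + (size_t)bins * gb] += 1.0;
  }
  std::vector<double> pf(bins, 0.0), pg(bins, 0.0);
  double n = (double)V;
  double hj = 0;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = joint[a + (size_t)bins * b] / n;
      if (p > 0) { hj -= p * std::log(p); pf[a] += p; pg[b] += p; }
    }
  double hf = 0, hg = 0;
  for (int a = 0; a < bins; ++a) {
    if (pf[a] > 0) hf -= pf[a] * std::log(pf[a]);
    if (pg[a] > 0) hg -= pg[a] * std::log(pg[a]);
  }
  return hf + hg - hj;
}
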