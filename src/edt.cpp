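#include <Rcpp.h>
using namespace Rcpp;

// Exact Euclidean distance transform by the separable lower-envelope
// (Felzenszwalb-Huttenlocher) algorithm, generalised to anisotropic
// sampling: one 1D squared-distance pass per axis with that axis' spacing.
// Input: mask (1 = foreground); output: distance from every voxel to the
// nearest zero (background) voxel, 0 on background.

static void dt1d(const double* f, double* d, int n, double s) {
  std::vector<int> vtx(n);
  std::vector<double> z(n + 1);
  int k = 0;
  vtx[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    double sq;
    while (true) {
      int p = vtx[k];
      if (f[p] == INFINITY) { // drop unusable parabola
        if (k == 0) { vtx[0] = q; z[0] = -INFINITY; z[1] = INFINITY; sq = NAN; break; }
        --k; continue;
      }
      sq = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sq <= z[k]) { --k; continue; }
      ++k; vtx[k] = q; z[k] = sq; z[k + 1] = INFINITY;
      break;
    }
  }
  // handle all-INF row
  if (f[vtx[0]] == INFINITY) { for (int q = 0; q < n; ++q) d[q] = INFINITY; return; }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = vtx[kk];
    double dq = s * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(NumericVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector out(V);
  std::vector<double> buf(V);
  for (size_t t = 0; t < V; ++t) buf[t] = mask[t] != 0.0 ? INFINITY : 0.0;

  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  std::vector<double> dl(line.size());

  // x-axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      dt1d(&buf[base], &dl[0], nx, spacing[0]);
      std::copy(dl.begin(), dl.begin() + nx, buf.begin() + base);
    }
  // y-axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = buf[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(&line[0], &dl[0], ny, spacing[1]);
      for (int j = 0; j < ny; ++j) buf[i + (size_t)nx * (j + (size_t)ny * k)] = dl[j];
    }
  // z-axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = buf[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(&line[0], &dl[0], nz, spacing[2]);
      for (int k = 0; k < nz; ++k) buf[i + (size_t)nx * (j + (size_t)ny * k)] = dl[k];
    }

  for (size_t t = 0; t < V; ++t) out[t] = std::sqrt(buf[t]);
  out.attr("dim") = dim;
  return out;
}
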