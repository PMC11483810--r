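#include <Rcpp.h>
using namespace Rcpp;

// Trilinear / nearest-neighbour pull-back resampling of a 3D scalar field.
// Arrays are column-major with dim (nx, ny, nz); voxel (i,j,k) sits at
// physical position origin + (i*dx, j*dy, k*dz) (voxel-centre convention,
// 0-based). Out-of-bounds samples take the fill value 0.

static inline double sample_linear(const double* v, int nx, int ny, int nz,
                                   double ci, double cj, double ck) {
  if (ci < -0.5 || cj < -0.5 || ck < -0.5 ||
      ci > nx - 0.5 || cj > ny - 0.5 || ck > nz - 0.5) return 0.0;
  int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj), k0 = (int)std::floor(ck);
  double fi = ci - i0, fj = cj - j0, fk = ck - k0;
  double acc = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    int k = k0 + dk; if (k < 0 || k >= nz) continue;
    double wk = dk ? fk : 1.0 - fk; if (wk == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj; if (j < 0 || j >= ny) continue;
      double wj = dj ? fj : 1.0 - fj; if (wj == 0.0) continue;
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di; if (i < 0 || i >= nx) continue;
        double wi = di ? fi : 1.0 - fi; if (wi == 0.0) continue;
        acc += wi * wj * wk * v[i + (size_t)nx * (j + (size_t)ny * k)];
      }
    }
  }
  return acc;
}

static inline double sample_nearest(const double* v, int nx, int ny, int nz,
                                    double ci, double cj, double ck) {
  int i = (int)std::lround(ci), j = (int)std::lround(cj), k = (int)std::lround(ck);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector values, IntegerVector dim_in,
                                  NumericVector origin_in, NumericVector spacing_in,
                                  IntegerVector dim_out, NumericVector origin_out,
                                  NumericVector spacing_out, NumericMatrix T,
                                  bool linear) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int mx = dim_out[0], my = dim_out[1], mz = dim_out[2];
  const double* v = values.begin();
  NumericVector out((size_t)mx * my * mz);
  double t00 = T(0,0), t01 = T(0,1), t02 = T(0,2), t03 = T(0,3);
  double t10 = T(1,0), t11 = T(1,1), t12 = T(1,2), t13 = T(1,3);
  double t20 = T(2,0), t21 = T(2,1), t22 = T(2,2), t23 = T(2,3);
  size_t idx = 0;
  for (int k = 0; k < mz; ++k) {
    double pz = origin_out[2] + k * spacing_out[2];
    for (int j = 0; j < my; ++j) {
      double py = origin_out[1] + j * spacing_out[1];
      for (int i = 0; i < mx; ++i, ++idx) {
        double px = origin_out[0] + i * spacing_out[0];
        double qx = t00 * px + t01 * py + t02 * pz + t03;
        double qy = t10 * px + t11 * py + t12 * pz + t13;
        double qz = t20 * px + t21 * py + t22 * pz + t23;
        double ci = (qx - origin_in[0]) / spacing_in[0];
        double cj = (qy - origin_in[1]) / spacing_in[1];
        double ck = (qz - origin_in[2]) / spacing_in[2];
        out[idx] = linear ? sample_linear(v, nx, ny, nz, ci, cj, ck)
                          : sample_nearest(v, nx, ny, nz, ci, cj, ck);
      }
    }
  }
  out.attr("dim") = dim_out;
  return out;
}

// Pull-back warp through a dense displacement field in voxel units of the
// same grid: out(v) = x(v + u(v)).
// [[Rcpp::export(name = ".ddf_warp_cpp")]]
NumericVector ddf_warp_cpp(NumericVector values, IntegerVector dim,
                           NumericVector ddf, bool linear) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  const double* v = values.begin();
  const double* u = ddf.begin();
  NumericVector out(V);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double ci = i + u[idx], cj = j + u[idx + V], ck = k + u[idx + 2 * V];
        out[idx] = linear ? sample_linear(v, nx, ny, nz, ci, cj, ck)
                          : sample_nearest(v, nx, ny, nz, ci, cj, ck);
      }
  out.attr("dim") = dim;
  return out;
}

// Gradient of sum(grad_out * warp(x, u)) with respect to the displacement
// field u: d out(v)/d u_c(v) is the spatial derivative of the trilinear
// interpolant of x at v + u(v).
// [[Rcpp::export(name = ".ddf_warp_grad_cpp")]]
NumericVector ddf_warp_grad_cpp(NumericVector values, IntegerVector dim,
                                NumericVector ddf, NumericVector grad_out) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  const double* v = values.begin();
  const double* u = ddf.begin();
  const double* g = grad_out.begin();
  NumericVector gu(3 * V);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double go = g[idx];
        if (go == 0.0) continue;
        double ci = i + u[idx], cj = j + u[idx + V], ck = k + u[idx + 2 * V];
        if (ci < -0.5 || cj < -0.5 || ck < -0.5 ||
            ci > nx - 0.5 || cj > ny - 0.5 || ck > nz - 0.5) continue;
        int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj), k0 = (int)std::floor(ck);
        double fi = ci - i0, fj = cj - j0, fk = ck - k0;
        double dx = 0.0, dy = 0.0, dz = 0.0;
        for (int dk = 0; dk <= 1; ++dk) {
          int kk = k0 + dk; if (kk < 0 || kk >= nz) continue;
          double wk = dk ? fk : 1.0 - fk, sk = dk ? 1.0 : -1.0;
          for (int dj = 0; dj <= 1; ++dj) {
            int jj = j0 + dj; if (jj < 0 || jj >= ny) continue;
            double wj = dj ? fj : 1.0 - fj, sj = dj ? 1.0 : -1.0;
            for (int di = 0; di <= 1; ++di) {
              int ii = i0 + di; if (ii < 0 || ii >= nx) continue;
              double wi = di ? fi : 1.0 - fi, si = di ? 1.0 : -1.0;
              double val = v[ii + (size_t)nx * (jj + (size_t)ny * kk)];
              dx += si * wj * wk * val;
              dy += wi * sj * wk * val;
              dz += wi * wj * sk * val;
            }
          }
        }
        gu[idx] = go * dx;
        gu[idx + V] = go * dy;
        gu[idx + 2 * V] = go * dz;
      }
  IntegerVector d4 = IntegerVector::create(nx, ny, nz, 3);
  gu.attr("dim") = d4;
  return gu;
}
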