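#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3x3x3 "same" convolution layers for the deformable-registration network.
// Feature maps are column-major arrays dim (nx, ny, nz, C); weights are
// (27*Cin) x Cout matrices whose rows run over (di, dj, dk, cin) with di
// fastest; zero padding of one voxel on every side. Convolutions are
// evaluated as im2col + GEMM over z-slabs to bound memory; the col matrix
// is laid out (voxels x 27*Cin) so the gather loops write contiguously.

static const int SLAB = 8;

// col: (nx*ny*(k_hi-k_lo+1)) x (27*cin), column-major
static void im2col_slab(const double* x, int nx, int ny, int nz, int cin,
                        int k_lo, int k_hi, arma::mat& col) {
  size_t plane = (size_t)nx * ny;
  size_t vol = plane * nz;
  int nk = k_hi - k_lo + 1;
  col.zeros(plane * nk, 27 * cin);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + vol * c;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int fcol = (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1)) + 27 * c;
          double* dstcol = col.colptr(fcol);
          for (int k = k_lo; k <= k_hi; ++k) {
            int ks = k + dk;
            if (ks < 0 || ks >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              int js = j + dj;
              if (js < 0 || js >= ny) continue;
              const double* src = xc + (size_t)nx * (js + (size_t)ny * ks) + di;
              double* dst = dstcol + plane * (k - k_lo) + (size_t)nx * j;
              int i_lo = std::max(0, -di), i_hi = std::min(nx, nx - di);
              std::copy(src + i_lo, src + i_hi, dst + i_lo);
            }
          }
        }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector dim, int cin,
                             NumericMatrix w, NumericVector bias) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int cout = w.ncol();
  size_t plane = (size_t)nx * ny, vol = plane * nz;
  NumericVector y(vol * cout);
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat col;
  for (int k0 = 0; k0 < nz; k0 += SLAB) {
    int k1 = std::min(nz - 1, k0 + SLAB - 1);
    im2col_slab(x.begin(), nx, ny, nz, cin, k0, k1, col);
    arma::mat out = col * W; // (voxels x cout)
    size_t nrow = out.n_rows;
    for (int c = 0; c < cout; ++c) {
      double b = bias[c];
      const double* oc = out.colptr(c);
      double* yc = y.begin() + vol * c + plane * k0;
      for (size_t t = 0; t < nrow; ++t) yc[t] = oc[t] + b;
    }
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector dim, int cin,
                    NumericMatrix w, NumericVector gy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int cout = w.ncol();
  size_t plane = (size_t)nx * ny, vol = plane * nz;
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat GW(w.nrow(), cout, arma::fill::zeros);
  NumericVector gx(vol * cin);
  NumericVector gb(cout);
  arma::mat col, gys;
  for (int k0 = 0; k0 < nz; k0 += SLAB) {
    int k1 = std::min(nz - 1, k0 + SLAB - 1);
    int nk = k1 - k0 + 1;
    size_t nrow = plane * nk;
    gys.set_size(nrow, cout);
    for (int c = 0; c < cout; ++c) {
      const double* g = gy.begin() + vol * c + plane * k0;
      std::copy(g, g + nrow, gys.colptr(c));
      gb[c] += std::accumulate(g, g + nrow, 0.0);
    }
    im2col_slab(x.begin(), nx, ny, nz, cin, k0, k1, col);
    GW += col.t() * gys;
    // input gradient: scatter of gcol = gys * W'
    arma::mat gcol = gys * W.t(); // (voxels x 27*cin)
    for (int c = 0; c < cin; ++c) {
      double* gxc = gx.begin() + vol * c;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int fcol = (di + 1) + 3 * ((dj + 1) + 3 * (dk + 1)) + 27 * c;
            const double* srccol = gcol.colptr(fcol);
            for (int k = k0; k <= k1; ++k) {
              int ks = k + dk;
              if (ks < 0 || ks >= nz) continue;
              for (int j = 0; j < ny; ++j) {
                int js = j + dj;
                if (js < 0 || js >= ny) continue;
                double* dst = gxc + (size_t)nx * (js + (size_t)ny * ks) + di;
                const double* src = srccol + plane * (k - k0) + (size_t)nx * j;
                int i_lo = std::max(0, -di), i_hi = std::min(nx, nx - di);
                for (int i = i_lo; i < i_hi; ++i) dst[i] += src[i];
              }
            }
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["gx"] = gx, _["gw"] = wrap(GW), _["gb"] = gb);
}

// 2x2x2 average pooling (dims must be even).
// [[Rcpp::export(name = ".avgpool2_fwd_cpp")]]
NumericVector avgpool2_fwd_cpp(NumericVector x, IntegerVector dim, int nc) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  size_t vin = (size_t)nx * ny * nz, vout = (size_t)mx * my * mz;
  NumericVector y(vout * nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + vin * c;
    double* yc = y.begin() + vout * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double s = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                s += xc[(2 * i + di) + (size_t)nx * ((2 * j + dj) + (size_t)ny * (2 * k + dk))];
          yc[i + (size_t)mx * (j + (size_t)my * k)] = s / 8.0;
        }
  }
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd_cpp")]]
NumericVector avgpool2_bwd_cpp(NumericVector gy, IntegerVector dim_in, int nc) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  size_t vin = (size_t)nx * ny * nz, vout = (size_t)mx * my * mz;
  NumericVector gx(vin * nc);
  for (int c = 0; c < nc; ++c) {
    const double* gc = gy.begin() + vout * c;
    double* xc = gx.begin() + vin * c;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double g = gc[i + (size_t)mx * (j + (size_t)my * k)] / 8.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                xc[(2 * i + di) + (size_t)nx * ((2 * j + dj) + (size_t)ny * (2 * k + dk))] = g;
        }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return gx;
}

// 2x nearest-neighbour upsampling.
// [[Rcpp::export(name = ".upsample2_fwd_cpp")]]
NumericVector upsample2_fwd_cpp(NumericVector x, IntegerVector dim, int nc) {
  int mx = dim[0], my = dim[1], mz = dim[2];
  int nx = mx * 2, ny = my * 2, nz = mz * 2;
  size_t vin = (size_t)mx * my * mz, vout = (size_t)nx * ny * nz;
  NumericVector y(vout * nc);
  for (int c = 0; c < nc; ++c) {
    const double* xc = x.begin() + vin * c;
    double* yc = y.begin() + vout * c;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const double* row = xc + (size_t)mx * ((j / 2) + (size_t)my * (k / 2));
        double* dst = yc + (size_t)nx * (j + (size_t)ny * k);
        for (int i = 0; i < nx; ++i) dst[i] = row[i / 2];
      }
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd_cpp")]]
NumericVector upsample2_bwd_cpp(NumericVector gy, IntegerVector dim_out, int nc) {
  int nx = dim_out[0], ny = dim_out[1], nz = dim_out[2];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  size_t vin = (size_t)mx * my * mz, vout = (size_t)nx * ny * nz;
  NumericVector gx(vin * nc);
  for (int c = 0; c < nc; ++c) {
    const double* gc = gy.begin() + vout * c;
    double* xc = gx.begin() + vin * c;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const double* src = gc + (size_t)nx * (j + (size_t)ny * k);
        double* dst = xc + (size_t)mx * ((j / 2) + (size_t)my * (k / 2));
        for (int i = 0; i < nx; ++i) dst[i / 2] += src[i];
      }
  }
  gx.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return gx;
}
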