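#include <Rcpp.h>
using namespace Rcpp;

// Bending energy of a dense displacement field (voxel-unit central second
// differences): mean over voxels of the squared Frobenius norm of the
// per-component Hessian, with stencils evaluated only where their support
// lies inside the grid (mixed entries weighted twice). The gradient applies
// the (symmetric) stencils as their own adjoints.

// [[Rcpp::export(name = ".bending_energy_cpp")]]
List bending_energy_cpp(NumericVector vec, IntegerVector dim, bool want_grad) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector grad(want_grad ? 3 * V : 0);
  double total = 0.0;
  const int pairs[6][2] = {{0,0},{1,1},{2,2},{0,1},{0,2},{1,2}};
  const double wts[6] = {1,1,1,2,2,2};
  std::vector<double> s(V);
  const int stride[3] = {1, nx, nx * ny};

  for (int c = 0; c < 3; ++c) {
    const double* u = vec.begin() + V * c;
    double* g = want_grad ? grad.begin() + V * c : (double*)nullptr;
    for (int t = 0; t < 6; ++t) {
      int a = pairs[t][0], b = pairs[t][1];
      std::fill(s.begin(), s.end(), 0.0);
      int lo[3] = {0, 0, 0}, hi[3] = {nx - 1, ny - 1, nz - 1};
      lo[a] = 1; hi[a] -= 1; lo[b] = std::max(lo[b], 1); hi[b] = std::min(hi[b], (b==0?nx:(b==1?ny:nz)) - 2);
      size_t sa = stride[a], sb = stride[b];
      for (int k = lo[2]; k <= hi[2]; ++k)
        for (int j = lo[1]; j <= hi[1]; ++j) {
          size_t base = (size_t)nx * (j + (size_t)ny * k);
          if (a == b) {
            for (int i = lo[0]; i <= hi[0]; ++i) {
              size_t v = base + i;
              s[v] = u[v + sa] - 2.0 * u[v] + u[v - sa];
            }
          } else {
            for (int i = lo[0]; i <= hi[0]; ++i) {
              size_t v = base + i;
              s[v] = (u[v + sa + sb] - u[v + sa - sb] - u[v - sa + sb] + u[v - sa - sb]) / 4.0;
            }
          }
        }
      double acc = 0.0;
      for (size_t v = 0; v < V; ++v) acc += s[v] * s[v];
      total += wts[t] * acc;
      if (want_grad) {
        // adjoint: same stencil applied to s (zero-filled outside), scaled
        double w2 = 2.0 * wts[t] / (double)V;
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
              size_t v = i + (size_t)nx * (j + (size_t)ny * k);
              double val;
              if (a == b) {
                double sp = 0, sm = 0;
                int ia = (a==0? i : (a==1? j : k));
                int na = (a==0? nx : (a==1? ny : nz));
                sp = (ia + 1 < na) ? s[v + sa] : 0.0;
                sm = (ia - 1 >= 0) ? s[v - sa] : 0.0;
                val = sp - 2.0 * s[v] + sm;
              } else {
                int ia = (a==0? i : (a==1? j : k));
                int ib = (b==0? i : (b==1? j : k));
                int na = (a==0? nx : (a==1? ny : nz));
                int nb = (b==0? nx : (b==1? ny : nz));
                double pp = (ia+1<na && ib+1<nb) ? s[v + sa + sb] : 0.0;
                double pm = (ia+1<na && ib-1>=0) ? s[v + sa - sb] : 0.0;
                double mp = (ia-1>=0 && ib+1<nb) ? s[v - sa + sb] : 0.0;
                double mm = (ia-1>=0 && ib-1>=0) ? s[v - sa - sb] : 0.0;
                val = (pp - pm - mp + mm) / 4.0;
              }
              g[v] += w2 * val;
            }
      }
    }
  }
  if (want_grad) grad.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["value"] = total / (double)V, _["grad"] = grad);
}
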