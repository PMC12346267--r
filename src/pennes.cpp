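// Pennes bioheat solver: implicit locally-one-dimensional (LOD) splitting of
// backward Euler. Each step performs three tridiagonal solves per grid line
// along x, y, z with harmonic-mean face conductivities; the perfusion sink
// and absorbed optical power enter the first sweep (perfusion implicitly).
// The outermost voxel shell is pinned (Dirichlet) at per-medium temperatures.
// The tridiagonal coefficients do not depend on time, so each line's LU
// factorization is computed once; the time loop runs only the O(n) rhs
// elimination and back substitution, with the inner loops contiguous in
// memory for every sweep direction.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct AxisFactors {
  // per-voxel: lower multiplier m, upper coefficient c, reciprocal of the
  // eliminated diagonal
  std::vector<double> m, c, inv_b;
};

}  // namespace

// [[Rcpp::export(name = ".pennes_lod_cpp")]]
List pennes_lod_cpp(IntegerVector labels, IntegerVector dims, double voxel_mm,
                    NumericMatrix thermal,  // rows per label: rho, c, k, w_perf
                    double rho_b, double c_b, double T_a,
                    NumericVector pin_temp,  // per label, also initial T
                    IntegerVector pin_label,  // per label: 1 = hold entire region fixed
                    NumericVector Q,         // W/m^3 per voxel
                    double dt, int n_steps, int record_every,
                    IntegerVector probe_idx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nv = (size_t)nx * ny * nz;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double dx = voxel_mm * 1e-3;  // m
  const double inv_dx2 = 1.0 / (dx * dx);
  const int n_lab = thermal.nrow();
  std::vector<double> rcdt_l(n_lab), kap(n_lab), perf_l(n_lab);
  for (int l = 0; l < n_lab; ++l) {
    rcdt_l[l] = thermal(l, 0) * thermal(l, 1) / dt;
    kap[l] = thermal(l, 2);
    perf_l[l] = thermal(l, 3) * rho_b * c_b;
  }

  std::vector<double> T(nv), rcdt(nv), src(nv);
  std::vector<uint8_t> pin(nv, 0);
  std::vector<int> lab(nv);
  for (size_t v = 0; v < nv; ++v) {
    lab[v] = labels[v] - 1;
    T[v] = pin_temp[lab[v]];
    rcdt[v] = rcdt_l[lab[v]];
    src[v] = Q[v] + perf_l[lab[v]] * T_a;
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t v = sx * i + sy * j + sz * k;
        if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
            k == 0 || k == nz - 1 || pin_label[lab[v]])
          pin[v] = 1;
      }

  auto hmean = [](double a, double b) {
    return (a + b > 0) ? 2.0 * a * b / (a + b) : 0.0;
  };

  // factor the tridiagonal system of one axis; with_extra adds the implicit
  // perfusion term to the diagonal (first sweep only)
  auto factor_axis = [&](size_t stride, int n_axis, bool with_extra) {
    AxisFactors f;
    f.m.assign(nv, 0.0); f.c.assign(nv, 0.0); f.inv_b.assign(nv, 1.0);
    std::vector<double> bdiag(nv);
    for (size_t v = 0; v < nv; ++v) {
      if (pin[v]) { bdiag[v] = 1.0; continue; }
      const double kw = hmean(kap[lab[v]], kap[lab[v - stride]]) * inv_dx2;
      const double ke = hmean(kap[lab[v]], kap[lab[v + stride]]) * inv_dx2;
      bdiag[v] = rcdt[v] + kw + ke + (with_extra ? perf_l[lab[v]] : 0.0);
      f.m[v] = -kw;   // lower coefficient (pre-elimination)
      f.c[v] = -ke;
    }
    // forward elimination, plane by plane so inner loops stay contiguous
    for (int i = 0; i < n_axis; ++i) {
      const size_t lo = (stride == sx) ? (size_t)i
                        : (stride == sy) ? (size_t)nx * i
                                         : sz * i;
      // iterate all voxels with axis-index i
      if (stride == sx) {
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j) {
            const size_t v = lo + sy * j + sz * k;
            if (i > 0 && !pin[v]) {
              const double m = f.m[v] * f.inv_b[v - stride];
              f.m[v] = m;
              bdiag[v] -= m * f.c[v - stride];
            } else f.m[v] = 0.0;
            f.inv_b[v] = 1.0 / bdiag[v];
          }
      } else if (stride == sy) {
        for (int k = 0; k < nz; ++k)
          for (int ii = 0; ii < nx; ++ii) {
            const size_t v = lo + sz * k + (size_t)ii;
            if (i > 0 && !pin[v]) {
              const double m = f.m[v] * f.inv_b[v - stride];
              f.m[v] = m;
              bdiag[v] -= m * f.c[v - stride];
            } else f.m[v] = 0.0;
            f.inv_b[v] = 1.0 / bdiag[v];
          }
      } else {
        for (size_t v = lo; v < lo + sz; ++v) {
          if (i > 0 && !pin[v]) {
            const double m = f.m[v] * f.inv_b[v - stride];
            f.m[v] = m;
            bdiag[v] -= m * f.c[v - stride];
          } else f.m[v] = 0.0;
          f.inv_b[v] = 1.0 / bdiag[v];
        }
      }
    }
    return f;
  };

  AxisFactors fx = factor_axis(sx, nx, true);
  AxisFactors fy = factor_axis(sy, ny, false);
  AxisFactors fz = factor_axis(sz, nz, false);

  std::vector<double> dd(nv);
  // one sweep: build rhs, eliminate, back-substitute into T
  auto sweep = [&](const AxisFactors& f, size_t stride, int n_axis,
                   bool with_source) {
    if (with_source) {
      for (size_t v = 0; v < nv; ++v)
        dd[v] = pin[v] ? T[v] : rcdt[v] * T[v] + src[v];
    } else {
      for (size_t v = 0; v < nv; ++v)
        dd[v] = pin[v] ? T[v] : rcdt[v] * T[v];
    }
    // forward: dd[v] -= m[v] * dd[v - stride] in axis order
    if (stride == sx) {
      for (size_t base = 0; base < nv; base += nx)
        for (int i = 1; i < nx; ++i)
          dd[base + i] -= f.m[base + i] * dd[base + i - 1];
      for (size_t base = 0; base < nv; base += nx) {
        size_t v = base + nx - 1;
        dd[v] *= f.inv_b[v];
        for (int i = nx - 2; i >= 0; --i) {
          v = base + i;
          dd[v] = (dd[v] - f.c[v] * dd[v + 1]) * f.inv_b[v];
        }
      }
    } else if (stride == sy) {
      for (int k = 0; k < nz; ++k) {
        const size_t pk = sz * k;
        for (int j = 1; j < ny; ++j) {
          const size_t row = pk + sy * j;
          for (int i = 0; i < nx; ++i)
            dd[row + i] -= f.m[row + i] * dd[row + i - sy];
        }
        const size_t last = pk + sy * (ny - 1);
        for (int i = 0; i < nx; ++i) dd[last + i] *= f.inv_b[last + i];
        for (int j = ny - 2; j >= 0; --j) {
          const size_t row = pk + sy * j;
          for (int i = 0; i < nx; ++i)
            dd[row + i] = (dd[row + i] - f.c[row + i] * dd[row + i + sy]) *
                          f.inv_b[row + i];
        }
      }
    } else {
      for (int k = 1; k < nz; ++k) {
        const size_t pk = sz * k;
        for (size_t i = 0; i < sz; ++i)
          dd[pk + i] -= f.m[pk + i] * dd[pk + i - sz];
      }
      const size_t lastp = sz * (nz - 1);
      for (size_t i = 0; i < sz; ++i) dd[lastp + i] *= f.inv_b[lastp + i];
      for (int k = nz - 2; k >= 0; --k) {
        const size_t pk = sz * k;
        for (size_t i = 0; i < sz; ++i)
          dd[pk + i] = (dd[pk + i] - f.c[pk + i] * dd[pk + i + sz]) *
                       f.inv_b[pk + i];
      }
    }
    std::swap(T, dd);
  };

  std::vector<double> Tmax = T;
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix traces(n_rec, probe_idx.size());
  NumericVector rec_times(n_rec);
  int rec = 0;
  for (int p = 0; p < probe_idx.size(); ++p) traces(rec, p) = T[probe_idx[p]];
  rec_times[rec++] = 0.0;

  for (int step = 1; step <= n_steps; ++step) {
    sweep(fx, sx, nx, true);
    sweep(fy, sy, ny, false);
    sweep(fz, sz, nz, false);
    for (size_t v = 0; v < nv; ++v)
      if (T[v] > Tmax[v]) Tmax[v] = T[v];
    if (step % record_every == 0) {
      for (int p = 0; p < probe_idx.size(); ++p) traces(rec, p) = T[probe_idx[p]];
      rec_times[rec++] = step * dt;
    }
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["T_final"] = NumericVector(T.begin(), T.end()),
                      _["T_max"] = NumericVector(Tmax.begin(), Tmax.end()),
                      _["times"] = rec_times,
                      _["traces"] = traces);
}
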