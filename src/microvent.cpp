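// Low-level numerical kernels: separable Gaussian smoothing, 7-point
// Laplacian, trilinear sampling, field-based warping, and the symmetric
// Thirion Demons solver with a multiresolution pyramid.
//
// Volumes are column-major 3D arrays (R layout), dim = (nx, ny, nz), with
// voxel-center physical coordinates p = origin + index * spacing (0-based
// indices, micrometre units throughout).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

namespace {

struct Grid {
  int n[3];
  double sp[3];
  double org[3];
};

inline size_t idx3(const Grid& g, int i, int j, int k) {
  return (size_t)i + (size_t)g.n[0] * ((size_t)j + (size_t)g.n[1] * (size_t)k);
}

inline int reflect(int i, int n) {
  // reflect-101 style boundary; degenerates safely for n == 1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// In-place separable Gaussian smoothing; sigma per axis in voxel units.
void smooth3(std::vector<double>& a, const Grid& g, const double sigma[3]) {
  std::vector<double> tmp(a.size());
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0.0) continue;
    std::vector<double> k = gauss_kernel(sigma[ax]);
    int r = ((int)k.size() - 1) / 2;
    int n0 = g.n[0], n1 = g.n[1], n2 = g.n[2];
    for (int kk = 0; kk < n2; ++kk)
      for (int jj = 0; jj < n1; ++jj)
        for (int ii = 0; ii < n0; ++ii) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int i = ii, j = jj, kz = kk;
            if (ax == 0) i = reflect(ii + t, n0);
            else if (ax == 1) j = reflect(jj + t, n1);
            else kz = reflect(kk + t, n2);
            acc += k[t + r] * a[idx3(g, i, j, kz)];
          }
          tmp[idx3(g, ii, jj, kk)] = acc;
        }
    a.swap(tmp);
  }
}

// Trilinear sample at continuous voxel coordinates (clamped to the domain).
inline double trilin(const std::vector<double>& a, const Grid& g,
                     double x, double y, double z, bool* oob = nullptr) {
  if (oob && (x < 0 || y < 0 || z < 0 ||
              x > g.n[0] - 1 || y > g.n[1] - 1 || z > g.n[2] - 1))
    *oob = true;
  x = std::min(std::max(x, 0.0), (double)(g.n[0] - 1));
  y = std::min(std::max(y, 0.0), (double)(g.n[1] - 1));
  z = std::min(std::max(z, 0.0), (double)(g.n[2] - 1));
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  i0 = clampi(i0, 0, g.n[0] - 2 >= 0 ? g.n[0] - 2 : 0);
  j0 = clampi(j0, 0, g.n[1] - 2 >= 0 ? g.n[1] - 2 : 0);
  k0 = clampi(k0, 0, g.n[2] - 2 >= 0 ? g.n[2] - 2 : 0);
  int i1 = std::min(i0 + 1, g.n[0] - 1);
  int j1 = std::min(j0 + 1, g.n[1] - 1);
  int k1 = std::min(k0 + 1, g.n[2] - 1);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c000 = a[idx3(g, i0, j0, k0)], c100 = a[idx3(g, i1, j0, k0)];
  double c010 = a[idx3(g, i0, j1, k0)], c110 = a[idx3(g, i1, j1, k0)];
  double c001 = a[idx3(g, i0, j0, k1)], c101 = a[idx3(g, i1, j0, k1)];
  double c011 = a[idx3(g, i0, j1, k1)], c111 = a[idx3(g, i1, j1, k1)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

Grid grid_from(const IntegerVector& dim, const NumericVector& spacing,
               const NumericVector& origin) {
  Grid g;
  for (int i = 0; i < 3; ++i) {
    g.n[i] = dim[i];
    g.sp[i] = spacing[i];
    g.org[i] = origin.size() == 3 ? origin[i] : 0.0;
  }
  return g;
}

std::vector<double> to_vec(const NumericVector& v) {
  return std::vector<double>(v.begin(), v.end());
}

NumericVector to_R(const std::vector<double>& v, const Grid& g) {
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = IntegerVector::create(g.n[0], g.n[1], g.n[2]);
  return out;
}

// Central-difference gradient (per physical unit), replicate at edges.
void gradient3(const std::vector<double>& a, const Grid& g,
               std::vector<double>& gx, std::vector<double>& gy,
               std::vector<double>& gz) {
  size_t nn = a.size();
  gx.resize(nn); gy.resize(nn); gz.resize(nn);
  for (int k = 0; k < g.n[2]; ++k)
    for (int j = 0; j < g.n[1]; ++j)
      for (int i = 0; i < g.n[0]; ++i) {
        size_t id = idx3(g, i, j, k);
        int im = std::max(i - 1, 0), ip = std::min(i + 1, g.n[0] - 1);
        int jm = std::max(j - 1, 0), jp = std::min(j + 1, g.n[1] - 1);
        int km = std::max(k - 1, 0), kp = std::min(k + 1, g.n[2] - 1);
        gx[id] = (a[idx3(g, ip, j, k)] - a[idx3(g, im, j, k)]) / ((ip - im) * g.sp[0]);
        gy[id] = (a[idx3(g, i, jp, k)] - a[idx3(g, i, jm, k)]) / ((jp - jm) * g.sp[1]);
        gz[id] = (a[idx3(g, i, j, kp)] - a[idx3(g, i, j, km)]) / ((kp - km) * g.sp[2]);
      }
}

// Smooth + decimate by 2 along each axis.
void downsample2(const std::vector<double>& a, const Grid& g,
                 std::vector<double>& out, Grid& go) {
  std::vector<double> s = a;
  double sg[3] = {1.0, 1.0, 1.0};
  smooth3(s, g, sg);
  for (int i = 0; i < 3; ++i) {
    go.n[i] = (g.n[i] + 1) / 2;
    go.sp[i] = g.sp[i] * 2.0;
    go.org[i] = g.org[i];
  }
  out.resize((size_t)go.n[0] * go.n[1] * go.n[2]);
  for (int k = 0; k < go.n[2]; ++k)
    for (int j = 0; j < go.n[1]; ++j)
      for (int i = 0; i < go.n[0]; ++i)
        out[idx3(go, i, j, k)] = s[idx3(g, std::min(2 * i, g.n[0] - 1),
                                        std::min(2 * j, g.n[1] - 1),
                                        std::min(2 * k, g.n[2] - 1))];
}

// Resample a field component defined on grid gc at the voxel centers of gf
// (both share the same physical origin).
void resample_to(const std::vector<double>& a, const Grid& gc, const Grid& gf,
                 std::vector<double>& out) {
  out.resize((size_t)gf.n[0] * gf.n[1] * gf.n[2]);
  for (int k = 0; k < gf.n[2]; ++k)
    for (int j = 0; j < gf.n[1]; ++j)
      for (int i = 0; i < gf.n[0]; ++i) {
        double x = (gf.org[0] + i * gf.sp[0] - gc.org[0]) / gc.sp[0];
        double y = (gf.org[1] + j * gf.sp[1] - gc.org[1]) / gc.sp[1];
        double z = (gf.org[2] + k * gf.sp[2] - gc.org[2]) / gc.sp[2];
        out[idx3(gf, i, j, k)] = trilin(a, gc, x, y, z);
      }
}

double sd_of(const std::vector<double>& a) {
  double m = std::accumulate(a.begin(), a.end(), 0.0) / a.size();
  double s = 0.0;
  for (double v : a) s += (v - m) * (v - m);
  return std::sqrt(s / (a.size() - 1.0));
}

} // namespace

// [[Rcpp::export(name = ".gaussian_smooth_c")]]
NumericVector gaussian_smooth_c(NumericVector vol, IntegerVector dim,
                                NumericVector sigma_vox) {
  Grid g;
  for (int i = 0; i < 3; ++i) { g.n[i] = dim[i]; g.sp[i] = 1; g.org[i] = 0; }
  std::vector<double> a = to_vec(vol);
  double sg[3] = {sigma_vox[0], sigma_vox[1], sigma_vox[2]};
  smooth3(a, g, sg);
  return to_R(a, g);
}

// [[Rcpp::export(name = ".laplacian_c")]]
NumericVector laplacian_c(NumericVector vol, IntegerVector dim,
                          NumericVector spacing) {
  Grid g;
  for (int i = 0; i < 3; ++i) { g.n[i] = dim[i]; g.sp[i] = spacing[i]; g.org[i] = 0; }
  std::vector<double> a = to_vec(vol);
  std::vector<double> out(a.size());
  for (int k = 0; k < g.n[2]; ++k)
    for (int j = 0; j < g.n[1]; ++j)
      for (int i = 0; i < g.n[0]; ++i) {
        double c = a[idx3(g, i, j, k)];
        int im = std::max(i - 1, 0), ip = std::min(i + 1, g.n[0] - 1);
        int jm = std::max(j - 1, 0), jp = std::min(j + 1, g.n[1] - 1);
        int km = std::max(k - 1, 0), kp = std::min(k + 1, g.n[2] - 1);
        double lx = (a[idx3(g, im, j, k)] - 2 * c + a[idx3(g, ip, j, k)]) / (g.sp[0] * g.sp[0]);
        double ly = (a[idx3(g, i, jm, k)] - 2 * c + a[idx3(g, i, jp, k)]) / (g.sp[1] * g.sp[1]);
        double lz = (a[idx3(g, i, j, km)] - 2 * c + a[idx3(g, i, j, kp)]) / (g.sp[2] * g.sp[2]);
        out[idx3(g, i, j, k)] = lx + ly + lz;
      }
  return to_R(out, g);
}

// [[Rcpp::export(name = ".trilin_points_c")]]
NumericVector trilin_points_c(NumericVector vol, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix points) {
  Grid g = grid_from(dim, spacing, origin);
  std::vector<double> a = to_vec(vol);
  int np = points.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = (points(p, 0) - g.org[0]) / g.sp[0];
    double y = (points(p, 1) - g.org[1]) / g.sp[1];
    double z = (points(p, 2) - g.org[2]) / g.sp[2];
    out[p] = trilin(a, g, x, y, z);
  }
  return out;
}

// [[Rcpp::export(name = ".warp_c")]]
List warp_c(NumericVector moving, IntegerVector mdim, NumericVector mspacing,
            NumericVector morigin, IntegerVector fdim, NumericVector fspacing,
            NumericVector forigin, NumericVector u1, NumericVector u2,
            NumericVector u3, bool nearest) {
  Grid gm = grid_from(mdim, mspacing, morigin);
  Grid gf = grid_from(fdim, fspacing, forigin);
  std::vector<double> a = to_vec(moving);
  size_t nn = (size_t)gf.n[0] * gf.n[1] * gf.n[2];
  std::vector<double> out(nn);
  std::vector<double> U1 = to_vec(u1), U2 = to_vec(u2), U3 = to_vec(u3);
  long oob_count = 0;
  for (int k = 0; k < gf.n[2]; ++k)
    for (int j = 0; j < gf.n[1]; ++j)
      for (int i = 0; i < gf.n[0]; ++i) {
        size_t id = idx3(gf, i, j, k);
        double px = gf.org[0] + i * gf.sp[0] + U1[id];
        double py = gf.org[1] + j * gf.sp[1] + U2[id];
        double pz = gf.org[2] + k * gf.sp[2] + U3[id];
        double x = (px - gm.org[0]) / gm.sp[0];
        double y = (py - gm.org[1]) / gm.sp[1];
        double z = (pz - gm.org[2]) / gm.sp[2];
        bool oob = false;
        if (nearest) {
          if (x < -0.5 || y < -0.5 || z < -0.5 || x > gm.n[0] - 0.5 ||
              y > gm.n[1] - 0.5 || z > gm.n[2] - 0.5) oob = true;
          int ii = clampi((int)std::lround(x), 0, gm.n[0] - 1);
          int jj = clampi((int)std::lround(y), 0, gm.n[1] - 1);
          int kk = clampi((int)std::lround(z), 0, gm.n[2] - 1);
          out[id] = a[idx3(gm, ii, jj, kk)];
        } else {
          out[id] = trilin(a, gm, x, y, z, &oob);
        }
        if (oob) ++oob_count;
      }
  return List::create(_["data"] = to_R(out, gf),
                      _["out_of_domain"] = (double)oob_count);
}

// [[Rcpp::export(name = ".demons_core_c")]]
List demons_core_c(NumericVector fixed, NumericVector moving, IntegerVector dim,
                   NumericVector spacing, int levels, IntegerVector iterations,
                   double smoothing_sigma) {
  Grid g0;
  for (int i = 0; i < 3; ++i) { g0.n[i] = dim[i]; g0.sp[i] = spacing[i]; g0.org[i] = 0; }

  // intensity normalization so the force balance is scale-free
  std::vector<double> F0 = to_vec(fixed), M0 = to_vec(moving);
  double sF = sd_of(F0), sM = sd_of(M0);
  if (sF > 0) for (double& v : F0) v /= sF;
  if (sM > 0) for (double& v : M0) v /= sM;

  // pyramid, index 0 = full resolution
  std::vector<std::vector<double>> Fp(levels), Mp(levels);
  std::vector<Grid> Gp(levels);
  Fp[0] = F0; Mp[0] = M0; Gp[0] = g0;
  for (int l = 1; l < levels; ++l) {
    downsample2(Fp[l - 1], Gp[l - 1], Fp[l], Gp[l]);
    std::vector<double> tmp; Grid gt;
    downsample2(Mp[l - 1], Gp[l - 1], tmp, gt);
    Mp[l] = tmp;
  }

  std::vector<double> u1, u2, u3;
  NumericVector level_mse(levels);
  IntegerVector level_iters(levels);

  for (int l = levels - 1; l >= 0; --l) {
    const Grid& g = Gp[l];
    size_t nn = (size_t)g.n[0] * g.n[1] * g.n[2];
    if (l == levels - 1) {
      u1.assign(nn, 0.0); u2.assign(nn, 0.0); u3.assign(nn, 0.0);
    } else {
      std::vector<double> v1, v2, v3;
      resample_to(u1, Gp[l + 1], g, v1);
      resample_to(u2, Gp[l + 1], g, v2);
      resample_to(u3, Gp[l + 1], g, v3);
      u1.swap(v1); u2.swap(v2); u3.swap(v3);
    }
    const std::vector<double>& F = Fp[l];
    const std::vector<double>& M = Mp[l];
    std::vector<double> gFx, gFy, gFz, gMx, gMy, gMz;
    gradient3(F, g, gFx, gFy, gFz);
    gradient3(M, g, gMx, gMy, gMz);
    double msp = (g.sp[0] + g.sp[1] + g.sp[2]) / 3.0;
    double inv_msp2 = 1.0 / (msp * msp);
    int iters = iterations[levels - 1 - l]; // iterations given coarse -> fine
    level_iters[levels - 1 - l] = iters;
    double sg[3] = {smoothing_sigma, smoothing_sigma, smoothing_sigma};
    double mse = 0.0;
    for (int it = 0; it < iters; ++it) {
      mse = 0.0;
      for (int k = 0; k < g.n[2]; ++k)
        for (int j = 0; j < g.n[1]; ++j)
          for (int i = 0; i < g.n[0]; ++i) {
            size_t id = idx3(g, i, j, k);
            double x = i + u1[id] / g.sp[0];
            double y = j + u2[id] / g.sp[1];
            double z = k + u3[id] / g.sp[2];
            double m = trilin(M, g, x, y, z);
            double diff = F[id] - m;
            mse += diff * diff;
            double jx = 0.5 * (gFx[id] + trilin(gMx, g, x, y, z));
            double jy = 0.5 * (gFy[id] + trilin(gMy, g, x, y, z));
            double jz = 0.5 * (gFz[id] + trilin(gMz, g, x, y, z));
            double den = jx * jx + jy * jy + jz * jz + diff * diff * inv_msp2;
            if (den > 1e-12) {
              double s = diff / den;
              u1[id] += s * jx;
              u2[id] += s * jy;
              u3[id] += s * jz;
            }
          }
      smooth3(u1, g, sg);
      smooth3(u2, g, sg);
      smooth3(u3, g, sg);
      Rcpp::checkUserInterrupt();
    }
    level_mse[levels - 1 - l] = mse / nn;
  }

  return List::create(_["u1"] = to_R(u1, Gp[0]), _["u2"] = to_R(u2, Gp[0]),
                      _["u3"] = to_R(u3, Gp[0]),
                      _["level_mse"] = level_mse,
                      _["level_iterations"] = level_iters);
}

// Exact two-sided permutation p-value for Spearman's rho on midranks.
// Enumerates all n! permutations; intended for n <= 10.
// [[Rcpp::export(name = ".spearman_perm_c")]]
double spearman_perm_c(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> a(rx.begin(), rx.end()), b(ry.begin(), ry.end());
  double ma = std::accumulate(a.begin(), a.end(), 0.0) / n;
  double mb = std::accumulate(b.begin(), b.end(), 0.0) / n;
  for (double& v : a) v -= ma;
  for (double& v : b) v -= mb;
  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += a[i] * b[i];
  obs = std::fabs(obs);
  std::vector<int> perm(n);
  std::iota(perm.begin(), perm.end(), 0);
  std::sort(perm.begin(), perm.end());
  long count = 0, total = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += a[i] * b[perm[i]];
    if (std::fabs(s) >= obs - 1e-12) ++count;
    ++total;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)count / (double)total;
}
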