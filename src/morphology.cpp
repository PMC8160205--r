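// Voxel-volume kernels: 3-D median filter, separable Gaussian blur,
// 26-connected component labelling, signed Euclidean distance transform
// (Felzenszwalb & Huttenlocher), and isosurface area by marching
// tetrahedra with normal-corrected facet weighting.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int refl(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// [[Rcpp::export(name = ".cpp_median3d")]]
NumericVector cpp_median3d(NumericVector vol, int radius) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(vol.size());
  out.attr("dim") = d;
  int w = 2 * radius + 1;
  std::vector<double> buf(w * w * w);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -radius; dk <= radius; ++dk)
          for (int dj = -radius; dj <= radius; ++dj)
            for (int di = -radius; di <= radius; ++di) {
              int ii = refl(i + di, nx), jj = refl(j + dj, ny), kk = refl(k + dk, nz);
              buf[m++] = vol[ii + nx * (jj + ny * (size_t)kk)];
            }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[i + nx * (j + ny * (size_t)k)] = buf[m / 2];
      }
  return out;
}

// separable Gaussian, reflective edges, kernel truncated at 3 sigma
// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += ker[i + r]; }
  for (size_t i = 0; i < ker.size(); ++i) ker[i] /= s;
  NumericVector a = clone(vol), b(vol.size());
  int dims[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int n = dims[ax];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx3[3] = {i, j, k};
          size_t base = i + nx * (j + ny * (size_t)k);
          double acc = 0;
          for (int o = -r; o <= r; ++o) {
            int p = refl(idx3[ax] + o, n);
            acc += ker[o + r] * a[base + ((size_t)p - (size_t)idx3[ax]) * stride[ax]];
          }
          b[base] = acc;
        }
    std::swap(a, b);
  }
  a.attr("dim") = d;
  return a;
}

// [[Rcpp::export(name = ".cpp_largest_component")]]
LogicalVector cpp_largest_component(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = mask.size();
  std::vector<int> lab(n, 0);
  int cur = 0, best_lab = 0;
  size_t best_size = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    size_t sz = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back(); ++sz;
      int i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            size_t u = ii + nx * (jj + ny * (size_t)kk);
            if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
          }
    }
    if (sz > best_size) { best_size = sz; best_lab = cur; }
  }
  LogicalVector out(n);
  out.attr("dim") = d;
  for (size_t s = 0; s < n; ++s) out[s] = (lab[s] == best_lab);
  return out;
}

static void dt1d(const std::vector<double> &f, std::vector<double> &dout, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e20; z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    dout[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

static void edt3d(std::vector<double> &g, int nx, int ny, int nz) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), o(nmax);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[i + nx * (j + ny * (size_t)k)];
      dt1d(f, o, nx);
      for (int i = 0; i < nx; ++i) g[i + nx * (j + ny * (size_t)k)] = o[i];
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[i + nx * (j + ny * (size_t)k)];
      dt1d(f, o, ny);
      for (int j = 0; j < ny; ++j) g[i + nx * (j + ny * (size_t)k)] = o[j];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[i + nx * (j + ny * (size_t)k)];
      dt1d(f, o, nz);
      for (int k = 0; k < nz; ++k) g[i + nx * (j + ny * (size_t)k)] = o[k];
    }
}

// signed distance in voxel units: positive inside the mask
// [[Rcpp::export(name = ".cpp_signed_edt")]]
NumericVector cpp_signed_edt(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = mask.size();
  std::vector<double> din(n), dout(n);
  for (size_t s = 0; s < n; ++s) {
    din[s] = mask[s] ? 0.0 : 1e20;
    dout[s] = mask[s] ? 1e20 : 0.0;
  }
  edt3d(din, nx, ny, nz);
  edt3d(dout, nx, ny, nz);
  NumericVector out(n);
  out.attr("dim") = d;
  for (size_t s = 0; s < n; ++s) out[s] = std::sqrt(dout[s]) - std::sqrt(din[s]);
  return out;
}

struct P3 { double x, y, z; };
static inline P3 lerp(const P3 &a, const P3 &b, double va, double vb, double iso) {
  double t = (iso - va) / (vb - va);
  P3 p = {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
  return p;
}
static inline double dot3(const P3 &a, const P3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// trilinear-interpolated central-difference gradient of g at p
static P3 gradat(const NumericVector &g, int nx, int ny, int nz, const P3 &p) {
  int i0 = (int)std::floor(p.x), j0 = (int)std::floor(p.y), k0 = (int)std::floor(p.z);
  double fx = p.x - i0, fy = p.y - j0, fz = p.z - k0;
  P3 acc = {0, 0, 0};
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        int i = std::min(std::max(i0 + di, 0), nx - 1);
        int j = std::min(std::max(j0 + dj, 0), ny - 1);
        int k = std::min(std::max(k0 + dk, 0), nz - 1);
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        acc.x += w * 0.5 * (g[ip + nx * (j + ny * (size_t)k)] - g[im + nx * (j + ny * (size_t)k)]);
        acc.y += w * 0.5 * (g[i + nx * (jp + ny * (size_t)k)] - g[i + nx * (jm + ny * (size_t)k)]);
        acc.z += w * 0.5 * (g[i + nx * (j + ny * (size_t)kp)] - g[i + nx * (j + ny * (size_t)km)]);
      }
  return acc;
}

// isosurface area of `field` at `iso`; when correct = true each facet's
// area is projected onto the local surface normal estimated from `gfield`
// [[Rcpp::export(name = ".cpp_mt_area")]]
double cpp_mt_area(NumericVector field, double iso, NumericVector gfield, bool correct) {
  IntegerVector d = field.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  static const int co[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {{0,5,1,7},{0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7}};
  double area = 0.0;
  // lambda-free accumulation for portability
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double v[8]; P3 p[8];
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          v[c] = field[ii + nx * (jj + ny * (size_t)kk)];
          p[c].x = ii; p[c].y = jj; p[c].z = kk;
        }
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          double tv[4] = {v[T[0]], v[T[1]], v[T[2]], v[T[3]]};
          P3 tp[4] = {p[T[0]], p[T[1]], p[T[2]], p[T[3]]};
          int ab[4], na = 0;
          for (int c = 0; c < 4; ++c) if (tv[c] > iso) ab[na++] = c;
          if (na == 0 || na == 4) continue;
          P3 tris[2][3];
          int ntri = 0;
          if (na == 1 || na == 3) {
            int apex = -1;
            if (na == 1) apex = ab[0];
            else for (int c = 0; c < 4; ++c) {
              bool in = false;
              for (int q = 0; q < na; ++q) if (ab[q] == c) in = true;
              if (!in) apex = c;
            }
            int m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) tris[0][m++] = lerp(tp[apex], tp[c], tv[apex], tv[c], iso);
            ntri = 1;
          } else {
            int a0 = ab[0], a1 = ab[1], b0 = -1, b1 = -1;
            for (int c = 0; c < 4; ++c) if (c != a0 && c != a1) { if (b0 < 0) b0 = c; else b1 = c; }
            P3 q0 = lerp(tp[a0], tp[b0], tv[a0], tv[b0], iso);
            P3 q1 = lerp(tp[a0], tp[b1], tv[a0], tv[b1], iso);
            P3 q2 = lerp(tp[a1], tp[b1], tv[a1], tv[b1], iso);
            P3 q3 = lerp(tp[a1], tp[b0], tv[a1], tv[b0], iso);
            tris[0][0] = q0; tris[0][1] = q1; tris[0][2] = q2;
            tris[1][0] = q0; tris[1][1] = q2; tris[1][2] = q3;
            ntri = 2;
          }
          for (int tt = 0; tt < ntri; ++tt) {
            const P3 &A = tris[tt][0], &B = tris[tt][1], &C = tris[tt][2];
            P3 u = {B.x - A.x, B.y - A.y, B.z - A.z}, vv = {C.x - A.x, C.y - A.y, C.z - A.z};
            P3 nvec = {u.y * vv.z - u.z * vv.y, u.z * vv.x - u.x * vv.z, u.x * vv.y - u.y * vv.x};
            double n2 = std::sqrt(dot3(nvec, nvec));
            if (n2 <= 0) continue;
            double A_ = 0.5 * n2;
            if (!correct) { area += A_; continue; }
            P3 cen = {(A.x + B.x + C.x) / 3, (A.y + B.y + C.y) / 3, (A.z + B.z + C.z) / 3};
            P3 g = gradat(gfield, nx, ny, nz, cen);
            double gn = std::sqrt(dot3(g, g));
            if (gn < 1e-12) { area += A_; continue; }
            area += A_ * std::fabs(dot3(nvec, g)) / (n2 * gn);
          }
        }
      }
  return area;
}
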