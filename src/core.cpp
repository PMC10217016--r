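#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// All volumes are flat NumericVector/IntegerVector with voxel (z, y, x)
// (0-based here) at linear index z + nz*(y + ny*x), matching an R array of
// dim c(nz, ny, nx).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int nz, int ny, int nx, int r) {
  NumericVector out(vol.size());
  int w = 2 * r + 1;
  std::vector<double> buf(w * w * w);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = clampi(x + dx, 0, nx - 1);
          for (int dy = -r; dy <= r; ++dy) {
            int yy = clampi(y + dy, 0, ny - 1);
            for (int dz = -r; dz <= r; ++dz) {
              int zz = clampi(z + dz, 0, nz - 1);
              buf[k++] = vol[lin(zz, yy, xx, nz, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[lin(z, y, x, nz, ny)] = buf[k / 2];
      }
  return out;
}

// Non-local means with replicated borders; weight exp(-mean patch SSD / h^2),
// centre patch carries weight 1.
// [[Rcpp::export]]
NumericVector cpp_nlm3d(NumericVector vol, int nz, int ny, int nx,
                        double h, int pr, int sr) {
  NumericVector out(vol.size());
  if (h <= 0) { std::copy(vol.begin(), vol.end(), out.begin()); return out; }
  double h2 = h * h;
  int np = (2 * pr + 1) * (2 * pr + 1) * (2 * pr + 1);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double wsum = 1.0, acc = vol[lin(z, y, x, nz, ny)];
        for (int sx = -sr; sx <= sr; ++sx)
          for (int sy = -sr; sy <= sr; ++sy)
            for (int sz = -sr; sz <= sr; ++sz) {
              if (sx == 0 && sy == 0 && sz == 0) continue;
              double ssd = 0.0;
              for (int px = -pr; px <= pr; ++px) {
                int ax = clampi(x + px, 0, nx - 1);
                int bx = clampi(x + sx + px, 0, nx - 1);
                for (int py = -pr; py <= pr; ++py) {
                  int ay = clampi(y + py, 0, ny - 1);
                  int by = clampi(y + sy + py, 0, ny - 1);
                  for (int pz = -pr; pz <= pr; ++pz) {
                    int az = clampi(z + pz, 0, nz - 1);
                    int bz = clampi(z + sz + pz, 0, nz - 1);
                    double d = vol[lin(az, ay, ax, nz, ny)] -
                               vol[lin(bz, by, bx, nz, ny)];
                    ssd += d * d;
                  }
                }
              }
              double wgt = std::exp(-(ssd / np) / h2);
              int qz = clampi(z + sz, 0, nz - 1);
              int qy = clampi(y + sy, 0, ny - 1);
              int qx = clampi(x + sx, 0, nx - 1);
              wsum += wgt;
              acc += wgt * vol[lin(qz, qy, qx, nz, ny)];
            }
        out[lin(z, y, x, nz, ny)] = acc / wsum;
      }
  return out;
}

// Pull-back rigid resampling. For every output voxel p (0-based (z,y,x)),
// sample the input at q = R (p - c) + c + t. R is 3x3 row-major acting on
// (z,y,x) vectors, t and c in voxels. Out-of-domain -> fill.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector vol, int nz, int ny, int nx,
                                 NumericVector R9, NumericVector t3,
                                 NumericVector c3, double fill, bool nearest,
                                 bool clamp) {
  NumericVector out((R_xlen_t)nz * ny * nx);
  double r00 = R9[0], r01 = R9[1], r02 = R9[2];
  double r10 = R9[3], r11 = R9[4], r12 = R9[5];
  double r20 = R9[6], r21 = R9[7], r22 = R9[8];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double vz = z - c3[0], vy = y - c3[1], vx = x - c3[2];
        double qz = r00 * vz + r01 * vy + r02 * vx + c3[0] + t3[0];
        double qy = r10 * vz + r11 * vy + r12 * vx + c3[1] + t3[1];
        double qx = r20 * vz + r21 * vy + r22 * vx + c3[2] + t3[2];
        double val;
        if (clamp) {
          if (qz < 0) qz = 0; if (qz > nz - 1) qz = nz - 1;
          if (qy < 0) qy = 0; if (qy > ny - 1) qy = ny - 1;
          if (qx < 0) qx = 0; if (qx > nx - 1) qx = nx - 1;
        }
        if (nearest) {
          int iz = (int)std::lround(qz), iy = (int)std::lround(qy),
              ix = (int)std::lround(qx);
          if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
            val = fill;
          else
            val = vol[lin(iz, iy, ix, nz, ny)];
        } else {
          if (qz < 0 || qz > nz - 1 || qy < 0 || qy > ny - 1 ||
              qx < 0 || qx > nx - 1) {
            val = fill;
          } else {
            int z0 = (int)std::floor(qz), y0 = (int)std::floor(qy),
                x0 = (int)std::floor(qx);
            int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
                x1 = std::min(x0 + 1, nx - 1);
            double fz = qz - z0, fy = qy - y0, fx = qx - x0;
            double c000 = vol[lin(z0, y0, x0, nz, ny)];
            double c100 = vol[lin(z1, y0, x0, nz, ny)];
            double c010 = vol[lin(z0, y1, x0, nz, ny)];
            double c110 = vol[lin(z1, y1, x0, nz, ny)];
            double c001 = vol[lin(z0, y0, x1, nz, ny)];
            double c101 = vol[lin(z1, y0, x1, nz, ny)];
            double c011 = vol[lin(z0, y1, x1, nz, ny)];
            double c111 = vol[lin(z1, y1, x1, nz, ny)];
            double c00 = c000 * (1 - fz) + c100 * fz;
            double c10 = c010 * (1 - fz) + c110 * fz;
            double c01 = c001 * (1 - fz) + c101 * fz;
            double c11 = c011 * (1 - fz) + c111 * fz;
            double c0 = c00 * (1 - fy) + c10 * fy;
            double c1 = c01 * (1 - fy) + c11 * fy;
            val = c0 * (1 - fx) + c1 * fx;
          }
        }
        out[lin(z, y, x, nz, ny)] = val;
      }
  return out;
}

// Normalised cross-correlation over voxels where both volumes are finite
// and (optionally) a mask is 0 (mask marks excluded voxels).
// [[Rcpp::export]]
double cpp_ncc(NumericVector a, NumericVector b, LogicalVector excl) {
  R_xlen_t n = a.size();
  bool use_excl = excl.size() == n;
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  R_xlen_t m = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double av = a[i], bv = b[i];
    if (!std::isfinite(av) || !std::isfinite(bv)) continue;
    if (use_excl && excl[i]) continue;
    sa += av; sb += bv; saa += av * av; sbb += bv * bv; sab += av * bv;
    ++m;
  }
  if (m < 8) return NA_REAL;
  double cov = sab - sa * sb / m;
  double va = saa - sa * sa / m, vb = sbb - sb * sb / m;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return cov / std::sqrt(va * vb);
}

// Block-mean downsampling by integer factor f along every axis.
// [[Rcpp::export]]
NumericVector cpp_downsample(NumericVector vol, int nz, int ny, int nx, int f) {
  int mz = nz / f, my = ny / f, mx = nx / f;
  NumericVector out((R_xlen_t)mz * my * mx);
  for (int x = 0; x < mx; ++x)
    for (int y = 0; y < my; ++y)
      for (int z = 0; z < mz; ++z) {
        double s = 0; int cnt = 0; bool na = false;
        for (int dx = 0; dx < f; ++dx)
          for (int dy = 0; dy < f; ++dy)
            for (int dz = 0; dz < f; ++dz) {
              double v = vol[lin(z * f + dz, y * f + dy, x * f + dx, nz, ny)];
              if (!std::isfinite(v)) { na = true; continue; }
              s += v; ++cnt;
            }
        out[(R_xlen_t)z + (R_xlen_t)mz * ((R_xlen_t)y + (R_xlen_t)my * x)] =
          (cnt == 0 || (na && cnt == 0)) ? NA_REAL : s / cnt;
      }
  return out;
}

// Weighted first-arrival (geodesic) times by Dijkstra on the voxel graph.
// slowness: per-voxel travel slowness in minutes per micrometre (Inf blocks);
// sources: 0-based linear indices with tau = 0. conn26 selects 26- vs
// 6-connectivity; edge cost = Euclidean step length (um) times the mean
// slowness of the two endpoints.
// [[Rcpp::export]]
NumericVector cpp_dijkstra_arrival(NumericVector slowness, int nz, int ny,
                                   int nx, IntegerVector sources,
                                   double voxel_um, bool conn26) {
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector tau(n, R_PosInf);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int i = 0; i < sources.size(); ++i) {
    R_xlen_t s = sources[i];
    if (s < 0 || s >= n) stop("source index out of range");
    if (std::isfinite(slowness[s])) { tau[s] = 0.0; pq.push(QE(0.0, s)); }
  }
  // neighbour offsets
  std::vector<int> oz, oy, ox; std::vector<double> olen;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int nrm = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (!conn26 && nrm > 1) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
        olen.push_back(std::sqrt((double)(dz * dz + dy * dy + dx * dx)) *
                       voxel_um);
      }
  size_t no = oz.size();
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; R_xlen_t i = top.second;
    if (d > tau[i]) continue;
    int x = (int)(i / ((R_xlen_t)nz * ny));
    int rem = (int)(i - (R_xlen_t)x * nz * ny);
    int y = rem / nz, z = rem % nz;
    double si = slowness[i];
    for (size_t k = 0; k < no; ++k) {
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = lin(zz, yy, xx, nz, ny);
      double sj = slowness[j];
      if (!std::isfinite(sj)) continue;
      double nd = d + olen[k] * 0.5 * (si + sj);
      if (nd < tau[j]) { tau[j] = nd; pq.push(QE(nd, j)); }
    }
  }
  return tau;
}

// Connected-component labelling (6 or 26 connectivity), labels 1..k by
// decreasing discovery order; 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int nz, int ny, int nx,
                                   bool conn26) {
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> oz, oy, ox;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (!conn26 && std::abs(dz) + std::abs(dy) + std::abs(dx) > 1) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  size_t no = oz.size();
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.clear(); stack.push_back(i); lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int x = (int)(j / ((R_xlen_t)nz * ny));
      int rem = (int)(j - (R_xlen_t)x * nz * ny);
      int y = rem / nz, z = rem % nz;
      for (size_t k = 0; k < no; ++k) {
        int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t q = lin(zz, yy, xx, nz, ny);
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Binary erosion/dilation with an explicit offset set (k x 3 matrix of
// (dz,dy,dx)). Erosion treats out-of-volume as foreground (replicate
// convention) so shapes touching the border are not eaten from outside.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, int nz, int ny, int nx,
                        IntegerMatrix off, bool dilate) {
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  int no = off.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool acc = dilate ? false : true;
        for (int k = 0; k < no; ++k) {
          int zz = z + off(k, 0), yy = y + off(k, 1), xx = x + off(k, 2);
          bool inside = zz >= 0 && zz < nz && yy >= 0 && yy < ny &&
                        xx >= 0 && xx < nx;
          bool v = inside ? (bool)mask[lin(zz, yy, xx, nz, ny)]
                          : (dilate ? false : true);
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[lin(z, y, x, nz, ny)] = acc;
      }
  return out;
}

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  // Lower envelope of parabolas (squared Euclidean distance transform, 1-D).
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0; v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform (in voxel units) of a binary
// mask: for each foreground voxel, squared distance to the nearest
// background voxel. Callers pad if the outside should count as background.
// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector mask, int nz, int ny, int nx) {
  // finite sentinel larger than any achievable squared distance, so the
  // parabola envelope stays numerically defined on all-foreground lines
  double big = (double)(nz + ny + nx + 3);
  big *= big;
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? big : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nz);
      for (int z = 0; z < nz; ++z) g[lin(z, y, x, nz, ny)] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, ny);
      for (int y = 0; y < ny; ++y) g[lin(z, y, x, nz, ny)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(z, y, x, nz, ny)];
      dt1d(f, d, v, zb, nx);
      for (int x = 0; x < nx; ++x) g[lin(z, y, x, nz, ny)] = d[x];
    }
  return g;
}
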