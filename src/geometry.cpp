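#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Index helpers: volumes are stored as R arrays, column-major, dims (nx, ny, nz),
// voxel (i,j,k) 0-based at linear index i + nx*(j + ny*k).
static inline size_t vidx(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// ---------------------------------------------------------------------------
// Mesh voxelization by vertical (z) ray parity.
//
// For each lateral subcolumn the crossing depths of the ray with the closed
// surface are collected; sorted crossings pair into inside intervals whose
// overlap with each voxel's z-extent gives an exact partial-volume fraction
// along z. supersample^2 subcolumns per voxel average the lateral fraction.
// supersample == 1 degenerates to binary voxel-center sampling (fraction 0/1),
// which is what the deterministic no-noise contract requires.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, NumericVector spacing,
                                IntegerVector dims, int supersample) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int s = supersample < 1 ? 1 : supersample;
  const int cx = nx * s, cy = ny * s;

  // tiny lateral jitter so rays never hit axis-aligned edges/vertices exactly
  const double jx = 3.11e-4 * sx, jy = 2.71e-4 * sy;

  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<std::vector<double>> cross((size_t)cx * cy);

  const int nf = F.nrow();
  for (int t = 0; t < nf; ++t) {
    const int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    const double x0 = V(a, 0), y0 = V(a, 1), z0 = V(a, 2);
    const double x1 = V(b, 0), y1 = V(b, 1), z1 = V(b, 2);
    const double x2 = V(c, 0), y2 = V(c, 1), z2 = V(c, 2);
    // 2D projected triangle; skip if degenerate (vertical wall: parity from caps)
    const double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(det) < 1e-14) continue;
    const double xmin = std::min(x0, std::min(x1, x2));
    const double xmax = std::max(x0, std::max(x1, x2));
    const double ymin = std::min(y0, std::min(y1, y2));
    const double ymax = std::max(y0, std::max(y1, y2));
    // subcolumn u has x = ox + (u + 0.5)/s * sx - 0.5*sx + jx
    int ulo = (int)std::floor(((xmin - jx - ox) / sx + 0.5) * s - 0.5);
    int uhi = (int)std::ceil(((xmax - jx - ox) / sx + 0.5) * s - 0.5);
    int vlo = (int)std::floor(((ymin - jy - oy) / sy + 0.5) * s - 0.5);
    int vhi = (int)std::ceil(((ymax - jy - oy) / sy + 0.5) * s - 0.5);
    ulo = std::max(ulo, 0); uhi = std::min(uhi, cx - 1);
    vlo = std::max(vlo, 0); vhi = std::min(vhi, cy - 1);
    for (int u = ulo; u <= uhi; ++u) {
      const double px = ox + ((u + 0.5) / s - 0.5) * sx + jx;
      for (int v = vlo; v <= vhi; ++v) {
        const double py = oy + ((v + 0.5) / s - 0.5) * sy + jy;
        const double l1 = ((px - x0) * (y2 - y0) - (py - y0) * (x2 - x0)) / det;
        const double l2 = ((x1 - x0) * (py - y0) - (y1 - y0) * (px - x0)) / det;
        if (l1 <= 0.0 || l2 <= 0.0 || l1 + l2 >= 1.0) continue;
        const double zc = z0 + l1 * (z1 - z0) + l2 * (z2 - z0);
        cross[(size_t)u + (size_t)cx * v].push_back(zc);
      }
    }
  }

  const double wsub = 1.0 / ((double)s * s);
  for (int u = 0; u < cx; ++u) {
    const int i = u / s;
    for (int v = 0; v < cy; ++v) {
      const int j = v / s;
      std::vector<double> &zs = cross[(size_t)u + (size_t)cx * v];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      const size_t np = zs.size() / 2;
      for (size_t p = 0; p < np; ++p) {
        const double zlo = zs[2 * p], zhi = zs[2 * p + 1];
        if (s == 1) {
          // voxel centers falling strictly inside [zlo, zhi]
          int klo = (int)std::ceil((zlo - oz) / sz);
          int khi = (int)std::floor((zhi - oz) / sz);
          klo = std::max(klo, 0); khi = std::min(khi, nz - 1);
          for (int k = klo; k <= khi; ++k) out[vidx(i, j, k, nx, ny)] = 1.0;
        } else {
          int klo = (int)std::floor((zlo - oz) / sz + 0.5);
          int khi = (int)std::floor((zhi - oz) / sz + 0.5);
          klo = std::max(klo, 0); khi = std::min(khi, nz - 1);
          for (int k = klo; k <= khi; ++k) {
            const double vz0 = oz + (k - 0.5) * sz, vz1 = vz0 + sz;
            const double ov = std::min(zhi, vz1) - std::max(zlo, vz0);
            if (ov > 0) out[vidx(i, j, k, nx, ny)] += ov / sz * wsub;
          }
        }
      }
    }
  }
  for (R_xlen_t q = 0; q < out.size(); ++q) if (out[q] > 1.0) out[q] = 1.0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope), anisotropic spacing, distance in mm to the nearest TRUE voxel.
// ---------------------------------------------------------------------------
// squared-distance sentinel standing in for "no feature on this line yet";
// large enough to dominate any in-grid squared distance, small enough to add safely
static const double EDT_BIG = 1e20;

static void edt_1d(std::vector<double> &f, std::vector<double> &d, double w2) {
  const int n = (int)f.size();
  std::vector<int> vtx(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  vtx[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sline;
    while (true) {
      const int p = vtx[k];
      sline = ((f[q] + w2 * (double)q * q) - (f[p] + w2 * (double)p * p)) /
              (2.0 * w2 * (q - p));
      if (sline <= zb[k] && k > 0) { --k; } else break;
    }
    if (sline <= zb[k] && k == 0) { vtx[0] = q; }
    else { ++k; vtx[k] = q; zb[k] = sline; }
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[kk + 1] < q) ++kk;
    const int p = vtx[kk];
    d[q] = f[p] + w2 * (double)(q - p) * (q - p);
    if (d[q] > EDT_BIG) d[q] = EDT_BIG;
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> D((size_t)nx * ny * nz);
  for (size_t q = 0; q < D.size(); ++q) D[q] = mask[q] ? 0.0 : EDT_BIG;

  std::vector<double> line, dl;
  // x pass
  line.resize(nx); dl.resize(nx);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) line[i] = D[vidx(i, j, k, nx, ny)];
    edt_1d(line, dl, spacing[0] * spacing[0]);
    for (int i = 0; i < nx; ++i) D[vidx(i, j, k, nx, ny)] = dl[i];
  }
  // y pass
  line.resize(ny); dl.resize(ny);
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) line[j] = D[vidx(i, j, k, nx, ny)];
    edt_1d(line, dl, spacing[1] * spacing[1]);
    for (int j = 0; j < ny; ++j) D[vidx(i, j, k, nx, ny)] = dl[j];
  }
  // z pass
  line.resize(nz); dl.resize(nz);
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) line[k] = D[vidx(i, j, k, nx, ny)];
    edt_1d(line, dl, spacing[2] * spacing[2]);
    for (int k = 0; k < nz; ++k) D[vidx(i, j, k, nx, ny)] = dl[k];
  }

  NumericVector out((R_xlen_t)nx * ny * nz);
  for (size_t q = 0; q < D.size(); ++q)
    out[q] = (D[q] >= EDT_BIG * 0.5) ? R_PosInf : std::sqrt(D[q]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Connected components, 6/18/26 connectivity, BFS, labels in discovery order.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int, 3>> nbr;
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
      if (m == 0) continue;
      if (connectivity == 6 && m > 1) continue;
      if (connectivity == 18 && m > 2) continue;
      nbr.push_back({dx, dy, dz});
    }
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<std::array<int, 3>> qq;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const size_t q0 = vidx(i, j, k, nx, ny);
    if (!mask[q0] || lab[q0] != 0) continue;
    ++next;
    lab[q0] = next;
    qq.push({i, j, k});
    while (!qq.empty()) {
      auto cur = qq.front(); qq.pop();
      for (auto &d : nbr) {
        const int ii = cur[0] + d[0], jj = cur[1] + d[1], kk = cur[2] + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        const size_t q = vidx(ii, jj, kk, nx, ny);
        if (mask[q] && lab[q] == 0) { lab[q] = next; qq.push({ii, jj, kk}); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Separable box (Chebyshev) dilation/erosion, radius r voxels.
// ---------------------------------------------------------------------------
static void box_pass(std::vector<unsigned char> &m, int nx, int ny, int nz,
                     int r, bool dilate, int axis) {
  std::vector<unsigned char> src = m;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    unsigned char acc = dilate ? 0 : 1;
    for (int d = -r; d <= r; ++d) {
      int ii = i, jj = j, kk = k;
      if (axis == 0) ii += d; else if (axis == 1) jj += d; else kk += d;
      unsigned char val;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        val = 0;  // outside the grid counts as background
      else val = src[vidx(ii, jj, kk, nx, ny)];
      if (dilate) { if (val) { acc = 1; break; } }
      else { if (!val) { acc = 0; break; } }
    }
    m[vidx(i, j, k, nx, ny)] = acc;
  }
}

// [[Rcpp::export]]
LogicalVector cpp_box_morph(LogicalVector mask, IntegerVector dims, int radius,
                            bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<unsigned char> m((size_t)nx * ny * nz);
  for (size_t q = 0; q < m.size(); ++q) m[q] = mask[q] ? 1 : 0;
  for (int a = 0; a < 3; ++a) box_pass(m, nx, ny, nz, radius, dilate, a);
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (size_t q = 0; q < m.size(); ++q) out[q] = m[q] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force nearest neighbour between point sets.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector d(na);
  IntegerVector idx(na);
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bi = j; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bi + 1;
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}

// closest squared distance from point p to triangle (a, b, c);
// uv (optional) receives the barycentric foot-point coordinates
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c, double *uv = 0) {
  double ab[3], ac[3], ap[3];
  for (int q = 0; q < 3; ++q) { ab[q] = b[q] - a[q]; ac[q] = c[q] - a[q]; ap[q] = p[q] - a[q]; }
  const double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  const double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double u, v;
  if (d1 <= 0.0 && d2 <= 0.0) { u = 0; v = 0; }
  else {
    double bp[3], cp[3];
    for (int q = 0; q < 3; ++q) { bp[q] = p[q] - b[q]; cp[q] = p[q] - c[q]; }
    const double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    const double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    const double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
    const double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
    if (d3 >= 0.0 && d4 <= d3) { u = 1; v = 0; }
    else if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 1; }
    else {
      const double vc = d1 * d4 - d3 * d2;
      const double vb = d5 * d2 - d1 * d6;
      const double va = d3 * d6 - d5 * d4;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { u = (d1 != d3) ? d1 / (d1 - d3) : 0; v = 0; }
      else if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { u = 0; v = (d2 != d6) ? d2 / (d2 - d6) : 0; }
      else if (va <= 0.0) {
        const double num = d4 - d3, den = (d4 - d3) + (d5 - d6);
        const double w = (den != 0) ? num / den : 0;
        u = 1 - w; v = w;
      } else {
        const double den = va + vb + vc;
        u = vb / den; v = vc / den;
      }
    }
  }
  double dd = 0;
  for (int q = 0; q < 3; ++q) {
    const double diff = a[q] + u * ab[q] + v * ac[q] - p[q];
    dd += diff * diff;
  }
  if (uv) { uv[0] = u; uv[1] = v; }
  return dd;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  std::vector<double> bb(6 * nf);
  std::vector<double> tv(9 * nf);
  for (int t = 0; t < nf; ++t) {
    for (int c = 0; c < 3; ++c) {
      const int vi = F(t, c) - 1;
      for (int q = 0; q < 3; ++q) tv[9 * t + 3 * c + q] = V(vi, q);
    }
    for (int q = 0; q < 3; ++q) {
      double lo = tv[9 * t + q], hi = lo;
      for (int c = 1; c < 3; ++c) {
        lo = std::min(lo, tv[9 * t + 3 * c + q]);
        hi = std::max(hi, tv[9 * t + 3 * c + q]);
      }
      bb[6 * t + q] = lo; bb[6 * t + 3 + q] = hi;
    }
  }
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < nf; ++t) {
      // quick reject on bbox distance
      double d2 = 0;
      for (int q = 0; q < 3; ++q) {
        double d = 0;
        if (p[q] < bb[6 * t + q]) d = bb[6 * t + q] - p[q];
        else if (p[q] > bb[6 * t + 3 + q]) d = p[q] - bb[6 * t + 3 + q];
        d2 += d * d;
      }
      if (d2 >= best) continue;
      const double dd = pt_tri_d2(p, &tv[9 * t], &tv[9 * t + 3], &tv[9 * t + 6]);
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_closest_point_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  std::vector<double> bb(6 * nf), tv(9 * nf);
  for (int t = 0; t < nf; ++t) {
    for (int c = 0; c < 3; ++c) {
      const int vi = F(t, c) - 1;
      for (int q = 0; q < 3; ++q) tv[9 * t + 3 * c + q] = V(vi, q);
    }
    for (int q = 0; q < 3; ++q) {
      double lo = tv[9 * t + q], hi = lo;
      for (int c = 1; c < 3; ++c) {
        lo = std::min(lo, tv[9 * t + 3 * c + q]);
        hi = std::max(hi, tv[9 * t + 3 * c + q]);
      }
      bb[6 * t + q] = lo; bb[6 * t + 3 + q] = hi;
    }
  }
  NumericVector dist(np);
  NumericMatrix foot(np, 3);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    double bu = 0, bv = 0;
    int bt = 0;
    for (int t = 0; t < nf; ++t) {
      double d2 = 0;
      for (int q = 0; q < 3; ++q) {
        double d = 0;
        if (p[q] < bb[6 * t + q]) d = bb[6 * t + q] - p[q];
        else if (p[q] > bb[6 * t + 3 + q]) d = p[q] - bb[6 * t + 3 + q];
        d2 += d * d;
      }
      if (d2 >= best) continue;
      double uv[2];
      const double dd = pt_tri_d2(p, &tv[9 * t], &tv[9 * t + 3], &tv[9 * t + 6], uv);
      if (dd < best) { best = dd; bt = t; bu = uv[0]; bv = uv[1]; }
    }
    dist[i] = std::sqrt(best);
    for (int q = 0; q < 3; ++q) {
      const double a = tv[9 * bt + q], b = tv[9 * bt + 3 + q], c = tv[9 * bt + 6 + q];
      foot(i, q) = a + bu * (b - a) + bv * (c - a);
    }
  }
  return List::create(_["dist"] = dist, _["points"] = foot);
}

// ---------------------------------------------------------------------------
// Boundary ("cuberille") surface of one label: one outward-oriented quad
// (two triangles) per exposed voxel face, vertices at voxel corners.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_boundary_surface(IntegerVector labels, IntegerVector dims, int target,
                          NumericVector origin, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<long long, int> cmap;
  std::vector<std::array<int, 3>> corners;
  std::vector<std::array<int, 3>> tris;
  const long long CX = nx + 1, CY = ny + 1;
  auto corner_id = [&](int i, int j, int k) -> int {
    const long long key = (long long)i + CX * ((long long)j + CY * (long long)k);
    auto it = cmap.find(key);
    if (it != cmap.end()) return it->second;
    const int id = (int)corners.size();
    cmap[key] = id;
    corners.push_back({i, j, k});
    return id;
  };
  const int e[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (labels[vidx(i, j, k, nx, ny)] != target) continue;
    for (int a = 0; a < 3; ++a) {
      const int u = (a + 1) % 3, v = (a + 2) % 3;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        const int ni = i + sgn * e[a][0], nj = j + sgn * e[a][1], nk = k + sgn * e[a][2];
        bool exposed = (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz);
        if (!exposed) exposed = labels[vidx(ni, nj, nk, nx, ny)] != target;
        if (!exposed) continue;
        int base[3] = {i, j, k};
        if (sgn > 0) { base[0] += e[a][0]; base[1] += e[a][1]; base[2] += e[a][2]; }
        int c0 = corner_id(base[0], base[1], base[2]);
        int c1, c2, c3;
        if (sgn > 0) {
          c1 = corner_id(base[0] + e[u][0], base[1] + e[u][1], base[2] + e[u][2]);
          c2 = corner_id(base[0] + e[u][0] + e[v][0], base[1] + e[u][1] + e[v][1],
                         base[2] + e[u][2] + e[v][2]);
          c3 = corner_id(base[0] + e[v][0], base[1] + e[v][1], base[2] + e[v][2]);
        } else {
          c1 = corner_id(base[0] + e[v][0], base[1] + e[v][1], base[2] + e[v][2]);
          c2 = corner_id(base[0] + e[u][0] + e[v][0], base[1] + e[u][1] + e[v][1],
                         base[2] + e[u][2] + e[v][2]);
          c3 = corner_id(base[0] + e[u][0], base[1] + e[u][1], base[2] + e[u][2]);
        }
        tris.push_back({c0, c1, c2});
        tris.push_back({c0, c2, c3});
      }
    }
  }
  NumericMatrix Vout((int)corners.size(), 3);
  for (size_t q = 0; q < corners.size(); ++q) {
    Vout(q, 0) = origin[0] + (corners[q][0] - 0.5) * spacing[0];
    Vout(q, 1) = origin[1] + (corners[q][1] - 0.5) * spacing[1];
    Vout(q, 2) = origin[2] + (corners[q][2] - 0.5) * spacing[2];
  }
  IntegerMatrix Fout((int)tris.size(), 3);
  for (size_t q = 0; q < tris.size(); ++q) {
    Fout(q, 0) = tris[q][0] + 1;
    Fout(q, 1) = tris[q][1] + 1;
    Fout(q, 2) = tris[q][2] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Taubin lambda|mu smoothing (volume-preserving when mu < -lambda < 0).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F, int iterations,
                                double lambda, double mu) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int>> adj(nv);
  auto add_edge = [&](int a, int b) {
    if (std::find(adj[a].begin(), adj[a].end(), b) == adj[a].end()) adj[a].push_back(b);
  };
  for (int t = 0; t < nf; ++t) {
    const int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    add_edge(a, b); add_edge(b, a);
    add_edge(b, c); add_edge(c, b);
    add_edge(c, a); add_edge(a, c);
  }
  std::vector<double> cur(3 * nv), nxt(3 * nv);
  for (int i = 0; i < nv; ++i) for (int q = 0; q < 3; ++q) cur[3 * i + q] = V(i, q);
  auto pass = [&](double w) {
    for (int i = 0; i < nv; ++i) {
      if (adj[i].empty()) {
        for (int q = 0; q < 3; ++q) nxt[3 * i + q] = cur[3 * i + q];
        continue;
      }
      double m[3] = {0, 0, 0};
      for (int nb : adj[i]) for (int q = 0; q < 3; ++q) m[q] += cur[3 * nb + q];
      for (int q = 0; q < 3; ++q) {
        const double lap = m[q] / adj[i].size() - cur[3 * i + q];
        nxt[3 * i + q] = cur[3 * i + q] + w * lap;
      }
    }
    cur.swap(nxt);
  };
  for (int it = 0; it < iterations; ++it) {
    pass(lambda);
    if (mu != 0.0) pass(mu);
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) for (int q = 0; q < 3; ++q) out(i, q) = cur[3 * i + q];
  return out;
}
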