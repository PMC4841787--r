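#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double *a, const double *b, double *o) {
  o[0] = a[0] - b[0];
  o[1] = a[1] - b[1];
  o[2] = a[2] - b[2];
}
static inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

// Squared distance from point p to triangle (a, b, c); closest point on the
// triangle found by barycentric region classification (Ericson 2005).
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3], q[3];
  sub3(b, a, ab);
  sub3(c, a, ac);
  sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    sub3(p, a, q);
    return dot3(q, q);
  }
  sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    sub3(p, b, q);
    return dot3(q, q);
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; i++) q[i] = p[i] - (a[i] + v * ab[i]);
    return dot3(q, q);
  }
  sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    sub3(p, c, q);
    return dot3(q, q);
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; i++) q[i] = p[i] - (a[i] + w * ac[i]);
    return dot3(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; i++) q[i] = p[i] - (b[i] + w * (c[i] - b[i]));
    return dot3(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; i++) q[i] = p[i] - (a[i] + ab[i] * v + ac[i] * w);
  return dot3(q, q);
}

// Minimum distance from each query point to a triangulated surface.
// Brute force over triangles with a cheap vertex-distance upper bound to
// prune; adequate at the mesh sizes this package works with.
// [[Rcpp::export(name = ".cpp_point_mesh_dist")]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); i++) {
    vx[i] = V(i, 0);
    vy[i] = V(i, 1);
    vz[i] = V(i, 2);
  }
  for (int ip = 0; ip < np; ip++) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; f++) {
      int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
      // lower bound: distance to vertex a minus max edge length is messy;
      // use quick reject on vertex a alone when it already exceeds best
      double da0 = p[0] - vx[ia], da1 = p[1] - vy[ia], da2 = p[2] - vz[ia];
      double d2a = da0 * da0 + da1 * da1 + da2 * da2;
      double ab0 = vx[ib] - vx[ia], ab1 = vy[ib] - vy[ia], ab2 = vz[ib] - vz[ia];
      double ac0 = vx[ic] - vx[ia], ac1 = vy[ic] - vy[ia], ac2 = vz[ic] - vz[ia];
      double e2 = std::max(ab0 * ab0 + ab1 * ab1 + ab2 * ab2,
                           ac0 * ac0 + ac1 * ac1 + ac2 * ac2);
      double lb = std::sqrt(d2a) - std::sqrt(e2);
      if (lb > 0 && lb * lb >= best) continue;
      double a[3] = {vx[ia], vy[ia], vz[ia]};
      double b[3] = {vx[ib], vy[ib], vz[ib]};
      double c[3] = {vx[ic], vy[ic], vz[ic]};
      double d2 = pt_tri_d2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// Moller-Trumbore; returns t (signed, line parameterization) or NA on miss.
static bool ray_tri_t(const double *o, const double *dir, const double *a,
                      const double *b, const double *c, double eps, double *t) {
  double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
  sub3(b, a, e1);
  sub3(c, a, e2);
  cross3(dir, e2, pvec);
  double det = dot3(e1, pvec);
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  sub3(o, a, tvec);
  double u = dot3(tvec, pvec) * inv;
  if (u < 0.0 || u > 1.0) return false;
  cross3(tvec, e1, qvec);
  double v = dot3(dir, qvec) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  *t = dot3(e2, qvec) * inv;
  return true;
}

// All signed line-surface intersection parameters t for each origin, along a
// single shared direction. Intersections with the interior of triangles only
// (|det| < eps treated as miss); callers dedupe near-identical t values that
// arise from hits on shared edges.
// [[Rcpp::export(name = ".cpp_line_mesh_hits")]]
List cpp_line_mesh_hits(NumericMatrix O, NumericVector dir, NumericMatrix V,
                        IntegerMatrix F) {
  int no = O.nrow(), nf = F.nrow();
  double d[3] = {dir[0], dir[1], dir[2]};
  List out(no);
  for (int io = 0; io < no; io++) {
    double o[3] = {O(io, 0), O(io, 1), O(io, 2)};
    std::vector<double> ts;
    for (int f = 0; f < nf; f++) {
      double a[3] = {V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2)};
      double b[3] = {V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2)};
      double c[3] = {V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2)};
      double t;
      if (ray_tri_t(o, d, a, b, c, 1e-12, &t)) ts.push_back(t);
    }
    std::sort(ts.begin(), ts.end());
    out[io] = NumericVector(ts.begin(), ts.end());
  }
  return out;
}

// Parity voxelization in voxel-index space: vertices already mapped so voxel
// centres sit at integer coordinates (0-based). Rays run along +x through
// each (y, z) centre, jittered off-grid so shared-edge hits cannot double
// count; a centre is foreground iff an odd number of crossings lies below it.
// [[Rcpp::export(name = ".cpp_voxelize_parity")]]
LogicalVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nf = F.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double jy = 7.1e-4, jz = 3.9e-4;  // fixed irrational-ish jitter
  const double dir[3] = {1.0, 0.0, 0.0};

  // triangle y/z bounding boxes for cheap rejection
  std::vector<double> ymin(nf), ymax(nf), zmin(nf), zmax(nf);
  for (int f = 0; f < nf; f++) {
    double y0 = V(F(f, 0), 1), y1 = V(F(f, 1), 1), y2 = V(F(f, 2), 1);
    double z0 = V(F(f, 0), 2), z1 = V(F(f, 1), 2), z2 = V(F(f, 2), 2);
    ymin[f] = std::min(y0, std::min(y1, y2));
    ymax[f] = std::max(y0, std::max(y1, y2));
    zmin[f] = std::min(z0, std::min(z1, z2));
    zmax[f] = std::max(z0, std::max(z1, z2));
  }
  std::vector<double> ts;
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      double oy = j + jy, oz = k + jz;
      double o[3] = {-1.0, oy, oz};
      ts.clear();
      for (int f = 0; f < nf; f++) {
        if (oy < ymin[f] || oy > ymax[f] || oz < zmin[f] || oz > zmax[f])
          continue;
        double a[3] = {V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2)};
        double b[3] = {V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2)};
        double c[3] = {V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2)};
        double t;
        if (ray_tri_t(o, dir, a, b, c, 1e-12, &t)) ts.push_back(t - 1.0);
      }
      std::sort(ts.begin(), ts.end());
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      size_t ptr = 0;
      bool inside = false;
      for (int i = 0; i < nx; i++) {
        while (ptr < ts.size() && ts[ptr] < (double)i) {
          inside = !inside;
          ptr++;
        }
        out[base + i] = inside;
      }
    }
  }
  return out;
}

// Trilinear (or nearest) interpolation of a 3D array at points given in
// 0-based voxel coordinates; coordinates are clamped to the grid.
// [[Rcpp::export(name = ".cpp_interp3")]]
NumericVector cpp_interp3(NumericVector arr, IntegerVector dim,
                          NumericMatrix P, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = P.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ip++) {
    double x = P(ip, 0), y = P(ip, 1), z = P(ip, 2);
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    if (nearest) {
      int i = (int)std::lround(x), j = (int)std::lround(y),
          k = (int)std::lround(z);
      out[ip] = arr[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = std::max(nx - 2, 0);
    if (j0 > ny - 2) j0 = std::max(ny - 2, 0);
    if (k0 > nz - 2) k0 = std::max(nz - 2, 0);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    #define A(i, j, k) arr[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
    double c00 = A(i0, j0, k0) * (1 - fx) + A(i1, j0, k0) * fx;
    double c10 = A(i0, j1, k0) * (1 - fx) + A(i1, j1, k0) * fx;
    double c01 = A(i0, j0, k1) * (1 - fx) + A(i1, j0, k1) * fx;
    double c11 = A(i0, j1, k1) * (1 - fx) + A(i1, j1, k1) * fx;
    #undef A
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[ip] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
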