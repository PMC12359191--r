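#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Brute-force geometric queries against triangle soups. Sizes in this
// package stay small enough (<= a few 10^3 triangles against <= 10^6 query
// points) that O(P*T) with tight inner loops is adequate.

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// squared distance point-triangle (Ericson, Real-Time Collision Detection)
static double pt_tri_d2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx = a[0]; qy = a[1]; qz = a[2]; }
  else {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0 && d4 <= d3) { qx = b[0]; qy = b[1]; qz = b[2]; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        qx = a[0] + v * ab[0]; qy = a[1] + v * ab[1]; qz = a[2] + v * ab[2];
      } else {
        double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
        double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
        if (d6 >= 0 && d5 <= d6) { qx = c[0]; qy = c[1]; qz = c[2]; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            qx = a[0] + w * ac[0]; qy = a[1] + w * ac[1]; qz = a[2] + w * ac[2];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              qx = b[0] + w * (c[0] - b[0]);
              qy = b[1] + w * (c[1] - b[1]);
              qz = b[2] + w * (c[2] - b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              qx = a[0] + ab[0] * v + ac[0] * w;
              qy = a[1] + ab[1] * v + ac[1] * w;
              qz = a[2] + ab[2] * v + ac[2] * w;
            }
          }
        }
      }
    }
  }
  double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export(name = ".pt_mesh_distance")]]
NumericVector pt_mesh_distance(NumericMatrix P, NumericMatrix V,
                               IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> tri(9 * nf);
  for (int t = 0; t < nf; ++t)
    for (int m = 0; m < 3; ++m)
      for (int c = 0; c < 3; ++c)
        tri[9 * t + 3 * m + c] = V(F(t, m) - 1, c);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    for (int t = 0; t < nf; ++t) {
      double d2 = pt_tri_d2(p, &tri[9 * t], &tri[9 * t + 3], &tri[9 * t + 6]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Moller-Trumbore ray/triangle; returns t > 0 or -1.
static double ray_tri(const double* o, const double* d, const double* a,
                      const double* b, const double* c, bool* edge_hit) {
  const double EPS = 1e-12;
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double pv[3] = {d[1] * e2[2] - d[2] * e2[1],
                  d[2] * e2[0] - d[0] * e2[2],
                  d[0] * e2[1] - d[1] * e2[0]};
  double det = dot3(e1, pv);
  if (std::abs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  double u = dot3(tv, pv) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return -1.0;
  double qv[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                  tv[2] * e1[0] - tv[0] * e1[2],
                  tv[0] * e1[1] - tv[1] * e1[0]};
  double v = dot3(d, qv) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return -1.0;
  double t = dot3(e2, qv) * inv;
  if (t <= 1e-12) return -1.0;
  if (u < 1e-8 || v < 1e-8 || u + v > 1.0 - 1e-8) *edge_hit = true;
  return t;
}

// Parity-based point-in-mesh for watertight meshes; retries with different
// ray directions when a ray grazes an edge.
// [[Rcpp::export(name = ".pts_in_mesh")]]
LogicalVector pts_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<double> tri(9 * nf);
  for (int t = 0; t < nf; ++t)
    for (int m = 0; m < 3; ++m)
      for (int c = 0; c < 3; ++c)
        tri[9 * t + 3 * m + c] = V(F(t, m) - 1, c);
  static const double dirs[5][3] = {
    {1.0, 0.0, 0.0},
    {0.267261241912424, 0.534522483824849, 0.801783725737273},
    {-0.577350269189626, 0.577350269189626, 0.577350269189626},
    {0.090909, -0.727272, 0.680413},
    {0.455842, 0.569803, -0.683763}};
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    bool inside = false;
    for (int attempt = 0; attempt < 5; ++attempt) {
      int crossings = 0;
      bool bad = false;
      for (int t = 0; t < nf && !bad; ++t) {
        bool edge_hit = false;
        double tt = ray_tri(p, dirs[attempt], &tri[9 * t], &tri[9 * t + 3],
                            &tri[9 * t + 6], &edge_hit);
        if (tt > 0) {
          if (edge_hit) bad = true;
          else ++crossings;
        }
      }
      if (!bad) { inside = (crossings % 2) == 1; break; }
      if (attempt == 4) inside = (crossings % 2) == 1; // best effort
    }
    out[i] = inside;
  }
  return out;
}

// Signed distance of a watertight mesh sampled on a regular grid. Unsigned
// distances are brute force; the sign is resolved per x-row with a single
// ray sweep (crossing parity accumulated along the row).
// [[Rcpp::export(name = ".grid_signed_distance")]]
NumericVector grid_signed_distance(NumericMatrix V, IntegerMatrix F,
                                   IntegerVector dims, NumericVector origin,
                                   NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2], nf = F.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> tri(9 * nf);
  for (int t = 0; t < nf; ++t)
    for (int m = 0; m < 3; ++m)
      for (int c = 0; c < 3; ++c)
        tri[9 * t + 3 * m + c] = V(F(t, m) - 1, c);
  double dirx[3] = {1.0, 0.0, 0.0};
  std::vector<double> xings;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      double o[3] = {origin[0] - 10.0 * spacing[0],
                     origin[1] + spacing[1] * j,
                     origin[2] + spacing[2] * k};
      xings.clear();
      bool bad = false;
      for (int t = 0; t < nf; ++t) {
        bool edge_hit = false;
        double tt = ray_tri(o, dirx, &tri[9 * t], &tri[9 * t + 3],
                            &tri[9 * t + 6], &edge_hit);
        if (tt > 0) {
          if (edge_hit) bad = true;
          xings.push_back(o[0] + tt);
        }
      }
      std::sort(xings.begin(), xings.end());
      for (int i = 0; i < nx; ++i) {
        double p[3] = {origin[0] + spacing[0] * i, o[1], o[2]};
        double best = R_PosInf;
        for (int t = 0; t < nf; ++t) {
          double d2 = pt_tri_d2(p, &tri[9 * t], &tri[9 * t + 3],
                                &tri[9 * t + 6]);
          if (d2 < best) best = d2;
        }
        int cross_before = 0;
        for (size_t m = 0; m < xings.size(); ++m)
          if (xings[m] < p[0]) ++cross_before;
        bool inside = (cross_before % 2) == 1;
        if (bad) {
          // fall back to the robust multi-ray test for this row point
          NumericMatrix P1(1, 3);
          P1(0, 0) = p[0]; P1(0, 1) = p[1]; P1(0, 2) = p[2];
          inside = pts_in_mesh(P1, V, F)[0];
        }
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] =
          inside ? -std::sqrt(best) : std::sqrt(best);
      }
    }
  }
  return out;
}

// Rasterize labeled tetrahedra onto a voxel grid (voxel-center containment).
// [[Rcpp::export(name = ".rasterize_tets")]]
IntegerVector rasterize_tets(NumericMatrix nodes, IntegerMatrix elems,
                             IntegerVector labels, IntegerVector dims,
                             NumericVector origin, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz); // 0 = unassigned
  int ne = elems.nrow();
  for (int e = 0; e < ne; ++e) {
    double P[4][3];
    for (int m = 0; m < 4; ++m)
      for (int c = 0; c < 3; ++c) P[m][c] = nodes(elems(e, m) - 1, c);
    // inverse of the edge matrix for barycentric coordinates
    double M[3][3];
    for (int c = 0; c < 3; ++c) {
      M[c][0] = P[1][c] - P[0][c];
      M[c][1] = P[2][c] - P[0][c];
      M[c][2] = P[3][c] - P[0][c];
    }
    double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
               - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
               + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    if (std::abs(det) < 1e-300) continue; // degenerate tet
    double inv[3][3];
    inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
    inv[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / det;
    inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
    inv[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / det;
    inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
    inv[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / det;
    inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
    inv[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / det;
    inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
    double lo[3], hi[3];
    for (int c = 0; c < 3; ++c) {
      lo[c] = hi[c] = P[0][c];
      for (int m = 1; m < 4; ++m) {
        lo[c] = std::min(lo[c], P[m][c]);
        hi[c] = std::max(hi[c], P[m][c]);
      }
    }
    int i0 = std::max(0, (int)std::ceil((lo[0] - origin[0]) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((hi[0] - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((lo[1] - origin[1]) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((hi[1] - origin[1]) / spacing[1]));
    int k0 = std::max(0, (int)std::ceil((lo[2] - origin[2]) / spacing[2]));
    int k1 = std::min(nz - 1, (int)std::floor((hi[2] - origin[2]) / spacing[2]));
    for (int k = k0; k <= k1; ++k) {
      for (int j = j0; j <= j1; ++j) {
        for (int i = i0; i <= i1; ++i) {
          double r[3] = {origin[0] + spacing[0] * i - P[0][0],
                         origin[1] + spacing[1] * j - P[0][1],
                         origin[2] + spacing[2] * k - P[0][2]};
          double b1 = inv[0][0] * r[0] + inv[0][1] * r[1] + inv[0][2] * r[2];
          double b2 = inv[1][0] * r[0] + inv[1][1] * r[1] + inv[1][2] * r[2];
          double b3 = inv[2][0] * r[0] + inv[2][1] * r[1] + inv[2][2] * r[2];
          double b0 = 1.0 - b1 - b2 - b3;
          const double eps = -1e-12;
          if (b0 >= eps && b1 >= eps && b2 >= eps && b3 >= eps) {
            out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = labels[e];
          }
        }
      }
    }
  }
  return out;
}
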