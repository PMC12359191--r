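#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Marching tetrahedra over a scalar field sampled on a regular grid.
// The cube at (i,j,k) is split into the six tetrahedra sharing the main
// diagonal (i,j,k)-(i+1,j+1,k+1); the decomposition is translation-invariant
// so shared cube faces are triangulated identically in neighboring cells,
// which makes the extracted surface closed and 2-manifold. "Inside" is
// field < iso; triangles are oriented with outward (field-increasing)
// normals. Crossing vertices are deduplicated via a global edge key.

struct MTBuilder {
  const double* f;
  int nx, ny, nz;
  double ox, oy, oz, hx, hy, hz, iso;
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // xyz triples
  std::vector<int> faces;      // vertex index triples (0-based)

  inline int gid(int i, int j, int k) const {
    return i + nx * (j + ny * k);
  }
  inline double val(int g) const {
    double v = f[g];
    // nudge exact hits off the isolevel so no vertex lies on the surface
    if (v == iso) v += (std::abs(iso) + 1.0) * 1e-12;
    return v;
  }
  inline void coord(int g, double* p) const {
    int i = g % nx, j = (g / nx) % ny, k = g / (nx * ny);
    p[0] = ox + hx * i; p[1] = oy + hy * j; p[2] = oz + hz * k;
  }
  int edge_point(int ga, int gb) {
    if (ga > gb) std::swap(ga, gb);
    uint64_t key = (uint64_t)ga * (uint64_t)(nx * ny * nz) + (uint64_t)gb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = val(ga), fb = val(gb);
    double t = (iso - fa) / (fb - fa);
    if (t < 1e-9) t = 1e-9;
    if (t > 1.0 - 1e-9) t = 1.0 - 1e-9;
    double pa[3], pb[3];
    coord(ga, pa); coord(gb, pb);
    int idx = (int)(verts.size() / 3);
    verts.push_back(pa[0] + t * (pb[0] - pa[0]));
    verts.push_back(pa[1] + t * (pb[1] - pa[1]));
    verts.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, idx);
    return idx;
  }
  void emit(int v0, int v1, int v2, const double* inward) {
    // orient so the normal points away from the inside region
    const double* a = &verts[3 * v0];
    const double* b = &verts[3 * v1];
    const double* c = &verts[3 * v2];
    double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double w[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double n[3] = {u[1] * w[2] - u[2] * w[1],
                   u[2] * w[0] - u[0] * w[2],
                   u[0] * w[1] - u[1] * w[0]};
    double d[3] = {a[0] - inward[0], a[1] - inward[1], a[2] - inward[2]};
    double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    if (dot >= 0) {
      faces.push_back(v0); faces.push_back(v1); faces.push_back(v2);
    } else {
      faces.push_back(v0); faces.push_back(v2); faces.push_back(v1);
    }
  }
  void do_tet(const int g[4]) {
    bool in[4];
    int nin = 0;
    for (int m = 0; m < 4; ++m) {
      in[m] = val(g[m]) < iso;
      if (in[m]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4];
    int a = 0, b = 0;
    for (int m = 0; m < 4; ++m) (in[m] ? ins[a++] : outs[b++]) = g[m];
    // reference point on the inside, used only to fix orientation
    double cin[3] = {0, 0, 0};
    for (int m = 0; m < a; ++m) {
      double p[3]; coord(ins[m], p);
      cin[0] += p[0] / a; cin[1] += p[1] / a; cin[2] += p[2] / a;
    }
    if (nin == 1) {
      int v0 = edge_point(ins[0], outs[0]);
      int v1 = edge_point(ins[0], outs[1]);
      int v2 = edge_point(ins[0], outs[2]);
      emit(v0, v1, v2, cin);
    } else if (nin == 3) {
      int v0 = edge_point(outs[0], ins[0]);
      int v1 = edge_point(outs[0], ins[1]);
      int v2 = edge_point(outs[0], ins[2]);
      emit(v0, v1, v2, cin);
    } else { // nin == 2: quad split into two triangles
      int v00 = edge_point(ins[0], outs[0]);
      int v01 = edge_point(ins[0], outs[1]);
      int v10 = edge_point(ins[1], outs[0]);
      int v11 = edge_point(ins[1], outs[1]);
      emit(v00, v01, v11, cin);
      emit(v00, v11, v10, cin);
    }
  }
};

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims,
                   NumericVector origin, NumericVector spacing, double iso) {
  MTBuilder B;
  B.f = REAL(field);
  B.nx = dims[0]; B.ny = dims[1]; B.nz = dims[2];
  B.ox = origin[0]; B.oy = origin[1]; B.oz = origin[2];
  B.hx = spacing[0]; B.hy = spacing[1]; B.hz = spacing[2];
  B.iso = iso;
  if ((R_xlen_t)B.nx * B.ny * B.nz != field.size())
    stop("field length does not match dims");
  // six tetrahedra: paths 0 -> a -> b -> 7 over the cube corner bits
  static const int tet_corners[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  for (int k = 0; k + 1 < B.nz; ++k) {
    for (int j = 0; j + 1 < B.ny; ++j) {
      for (int i = 0; i + 1 < B.nx; ++i) {
        int corner[8];
        for (int c = 0; c < 8; ++c) {
          corner[c] = B.gid(i + (c & 1), j + ((c >> 1) & 1),
                            k + ((c >> 2) & 1));
        }
        // quick reject: all corners same side
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          if (B.val(corner[c]) < B.iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int g[4];
          for (int m = 0; m < 4; ++m) g[m] = corner[tet_corners[t][m]];
          B.do_tet(g);
        }
      }
    }
  }
  int nv = (int)(B.verts.size() / 3), nf = (int)(B.faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v)
    for (int c = 0; c < 3; ++c) V(v, c) = B.verts[3 * v + c];
  for (int t = 0; t < nf; ++t)
    for (int c = 0; c < 3; ++c) F(t, c) = B.faces[3 * t + c] + 1; // 1-based
  return List::create(_["vertices"] = V, _["faces"] = F);
}
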