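#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Incremental 3-D convex hull. Facets are kept outward-oriented (an interior
// reference point has negative signed distance to every facet plane), so the
// enclosed volume follows from the divergence theorem as a sum of signed
// tetrahedra. Points closer to a plane than a scale-relative epsilon are
// treated as on it and never open a horizon, which keeps coplanar inputs
// (e.g. cube faces sampled densely) stable.

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // unit-ish normal and plane offset (n . x = off)
  bool alive;
};

static inline void plane(const std::vector<double>& X,
                         const std::vector<double>& Y,
                         const std::vector<double>& Z,
                         Face& f) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

static inline double sdist(const std::vector<double>& X,
                           const std::vector<double>& Y,
                           const std::vector<double>& Z,
                           const Face& f, int i) {
  double nrm = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  if (nrm == 0.0) return 0.0;
  return (f.nx * X[i] + f.ny * Y[i] + f.nz * Z[i] - f.off) / nrm;
}

static inline uint64_t ekey(int a, int b) {
  return (static_cast<uint64_t>(static_cast<uint32_t>(a)) << 32) |
         static_cast<uint32_t>(b);
}

// [[Rcpp::export(name = ".convex_hull_3d_cpp", rng = false)]]
List convex_hull_3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull in 3-D needs at least 4 points, got %d", n);
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }

  double lo[3] = {X[0], Y[0], Z[0]}, hi[3] = {X[0], Y[0], Z[0]};
  for (int i = 0; i < n; ++i) {
    lo[0] = std::min(lo[0], X[i]); hi[0] = std::max(hi[0], X[i]);
    lo[1] = std::min(lo[1], Y[i]); hi[1] = std::max(hi[1], Y[i]);
    lo[2] = std::min(lo[2], Z[i]); hi[2] = std::max(hi[2], Z[i]);
  }
  const double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                                (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                                (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag == 0.0) stop("degenerate input: all points identical");
  const double eps = 1e-10 * diag;

  // initial simplex: spread pair, then max-area, then max-volume point
  int i0 = 0, i1 = 0;
  {
    double best = -1.0;
    int ext[6];
    for (int d = 0; d < 3; ++d) {
      const std::vector<double>& C = (d == 0 ? X : (d == 1 ? Y : Z));
      int mi = 0, ma = 0;
      for (int i = 1; i < n; ++i) { if (C[i] < C[mi]) mi = i; if (C[i] > C[ma]) ma = i; }
      ext[2 * d] = mi; ext[2 * d + 1] = ma;
    }
    for (int p = 0; p < 6; ++p) for (int q = p + 1; q < 6; ++q) {
      int a = ext[p], b = ext[q];
      double dd = (X[a] - X[b]) * (X[a] - X[b]) + (Y[a] - Y[b]) * (Y[a] - Y[b]) +
                  (Z[a] - Z[b]) * (Z[a] - Z[b]);
      if (dd > best) { best = dd; i0 = a; i1 = b; }
    }
    if (best <= eps * eps) stop("degenerate input: all points coincide");
  }
  int i2 = -1;
  {
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
      double vx = X[i] - X[i0], vy = Y[i] - Y[i0], vz = Z[i] - Z[i0];
      double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
      double a2 = cx * cx + cy * cy + cz * cz;
      if (a2 > best) { best = a2; i2 = i; }
    }
    if (best <= eps * eps) stop("degenerate input: points are collinear");
  }
  int i3 = -1;
  double vol0 = 0.0;
  {
    Face f{i0, i1, i2, 0, 0, 0, 0, true};
    plane(X, Y, Z, f);
    double best = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = f.nx * X[i] + f.ny * Y[i] + f.nz * Z[i] - f.off;
      if (std::fabs(d) > std::fabs(best)) { best = d; i3 = i; }
    }
    double nrm = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (i3 < 0 || std::fabs(best) / nrm <= eps)
      stop("degenerate input: points are coplanar");
    vol0 = best;
  }

  std::vector<Face> faces;
  faces.reserve(256);
  // orient the initial tetrahedron outward w.r.t. its own centroid
  double ox = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  double oy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  double oz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;
  int tetra[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  (void)vol0;
  for (int k = 0; k < 4; ++k) {
    Face f{tetra[k][0], tetra[k][1], tetra[k][2], 0, 0, 0, 0, true};
    plane(X, Y, Z, f);
    if (f.nx * ox + f.ny * oy + f.nz * oz - f.off > 0) { std::swap(f.b, f.c); plane(X, Y, Z, f); }
    faces.push_back(f);
  }

  std::unordered_set<uint64_t> horizon_edges;
  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (int k = 0; k < static_cast<int>(faces.size()); ++k) {
      if (!faces[k].alive) continue;
      if (sdist(X, Y, Z, faces[k], i) > eps) visible.push_back(k);
    }
    if (visible.empty()) continue;
    horizon_edges.clear();
    for (int k : visible) {
      const Face& f = faces[k];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        uint64_t rev = ekey(e[j][1], e[j][0]);
        auto it = horizon_edges.find(rev);
        if (it != horizon_edges.end()) horizon_edges.erase(it);
        else horizon_edges.insert(ekey(e[j][0], e[j][1]));
      }
    }
    for (int k : visible) faces[k].alive = false;
    for (uint64_t key : horizon_edges) {
      int a = static_cast<int>(key >> 32), b = static_cast<int>(key & 0xffffffffu);
      Face f{a, b, i, 0, 0, 0, 0, true};
      plane(X, Y, Z, f);
      if (f.nx * ox + f.ny * oy + f.nz * oz - f.off > 0) { std::swap(f.b, f.c); plane(X, Y, Z, f); }
      faces.push_back(f);
    }
    // periodically drop dead faces to bound the scan cost
    if (faces.size() > 4096) {
      size_t w = 0;
      for (size_t k = 0; k < faces.size(); ++k) if (faces[k].alive) faces[w++] = faces[k];
      faces.resize(w);
    }
  }

  double vol = 0.0, area = 0.0;
  int nface = 0;
  std::unordered_set<int> verts;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    ++nface;
    verts.insert(f.a); verts.insert(f.b); verts.insert(f.c);
    double ax = X[f.a] - ox, ay = Y[f.a] - oy, az = Z[f.a] - oz;
    double bx = X[f.b] - ox, by = Y[f.b] - oy, bz = Z[f.b] - oz;
    double cx = X[f.c] - ox, cy = Y[f.c] - oy, cz = Z[f.c] - oz;
    vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
            az * (bx * cy - by * cx)) / 6.0;
    area += 0.5 * std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  }
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["n_faces"] = nface,
                      _["n_vertices"] = static_cast<int>(verts.size()));
}
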