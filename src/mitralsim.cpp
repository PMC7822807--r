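// XPBD solver core for the mitral valve model.
//
// Everything here is deliberately single-threaded and order-deterministic:
// constraint projections run in a fixed sequence (distance -> bending ->
// area -> cords -> collisions, each in index order) so that repeated runs
// are bit-identical. Units: mm, s; vertex masses are 1 for free vertices.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------------------
// point-triangle closest point (Ericson, Real-Time Collision Detection)
// ---------------------------------------------------------------------------

static V3 closest_point_triangle(const V3& p, const V3& a, const V3& b, const V3& c,
                                 double* bary = nullptr) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { if (bary) { bary[0] = 1; bary[1] = 0; bary[2] = 0; } return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { if (bary) { bary[0] = 0; bary[1] = 1; bary[2] = 0; } return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    if (bary) { bary[0] = 1 - v; bary[1] = v; bary[2] = 0; }
    return a + v * ab;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { if (bary) { bary[0] = 0; bary[1] = 0; bary[2] = 1; } return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    if (bary) { bary[0] = 1 - w; bary[1] = 0; bary[2] = w; }
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    if (bary) { bary[0] = 0; bary[1] = 1 - w; bary[2] = w; }
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  if (bary) { bary[0] = 1 - v - w; bary[1] = v; bary[2] = w; }
  return a + v * ab + w * ac;
}

// [[Rcpp::export]]
List cpp_point_triangle(NumericVector p, NumericVector a, NumericVector b, NumericVector c) {
  V3 P(p[0], p[1], p[2]), A(a[0], a[1], a[2]), B(b[0], b[1], b[2]), C(c[0], c[1], c[2]);
  double bary[3];
  V3 q = closest_point_triangle(P, A, B, C, bary);
  return List::create(_["distance"] = norm(P - q),
                      _["closest"] = NumericVector::create(q.x, q.y, q.z),
                      _["bary"] = NumericVector::create(bary[0], bary[1], bary[2]));
}

// ---------------------------------------------------------------------------
// AABB tree for point-to-mesh distance queries
// ---------------------------------------------------------------------------

struct BVHNode {
  double lo[3], hi[3];
  int left, right;       // children, or -1 if leaf
  int begin, end;        // triangle index range (into order) for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
};

static void bvh_bounds(const std::vector<V3>& cent, const NumericMatrix& pos,
                       const IntegerMatrix& tri, const std::vector<int>& order,
                       int begin, int end, BVHNode& nd) {
  for (int k = 0; k < 3; ++k) { nd.lo[k] = R_PosInf; nd.hi[k] = R_NegInf; }
  for (int t = begin; t < end; ++t) {
    int f = order[t];
    for (int v = 0; v < 3; ++v) {
      int id = tri(f, v) - 1;
      for (int k = 0; k < 3; ++k) {
        double c = pos(id, k);
        if (c < nd.lo[k]) nd.lo[k] = c;
        if (c > nd.hi[k]) nd.hi[k] = c;
      }
    }
  }
}

static int bvh_build(BVH& bvh, const std::vector<V3>& cent, const NumericMatrix& pos,
                     const IntegerMatrix& tri, int begin, int end) {
  BVHNode nd;
  bvh_bounds(cent, pos, tri, bvh.order, begin, end, nd);
  nd.left = nd.right = -1;
  nd.begin = begin; nd.end = end;
  int idx = (int)bvh.nodes.size();
  bvh.nodes.push_back(nd);
  if (end - begin > 4) {
    int axis = 0;
    double ext = nd.hi[0] - nd.lo[0];
    for (int k = 1; k < 3; ++k)
      if (nd.hi[k] - nd.lo[k] > ext) { ext = nd.hi[k] - nd.lo[k]; axis = k; }
    int mid = (begin + end) / 2;
    std::nth_element(bvh.order.begin() + begin, bvh.order.begin() + mid,
                     bvh.order.begin() + end,
                     [&](int a, int b) {
                       double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                       double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                       if (ca != cb) return ca < cb;
                       return a < b;   // deterministic tie-break
                     });
    int l = bvh_build(bvh, cent, pos, tri, begin, mid);
    int r = bvh_build(bvh, cent, pos, tri, mid, end);
    bvh.nodes[idx].left = l;
    bvh.nodes[idx].right = r;
  }
  return idx;
}

static inline double box_dist2(const BVHNode& nd, const V3& p) {
  double d2 = 0, c[3] = { p.x, p.y, p.z };
  for (int k = 0; k < 3; ++k) {
    double d = 0;
    if (c[k] < nd.lo[k]) d = nd.lo[k] - c[k];
    else if (c[k] > nd.hi[k]) d = c[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

// Exact minimum distance of each query point to the triangle mesh,
// BVH-accelerated; equals the brute-force minimum over all triangles.
// [[Rcpp::export]]
List cpp_points_to_mesh(NumericMatrix query, NumericMatrix pos, IntegerMatrix tri) {
  int m = tri.nrow(), nq = query.nrow();
  if (m == 0) stop("points_to_mesh: empty mesh");
  std::vector<V3> cent(m);
  for (int f = 0; f < m; ++f) {
    V3 s(0, 0, 0);
    for (int v = 0; v < 3; ++v) {
      int id = tri(f, v) - 1;
      s = s + V3(pos(id, 0), pos(id, 1), pos(id, 2));
    }
    cent[f] = (1.0 / 3.0) * s;
  }
  BVH bvh;
  bvh.order.resize(m);
  for (int f = 0; f < m; ++f) bvh.order[f] = f;
  bvh_build(bvh, cent, pos, tri, 0, m);

  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector tri_id(nq);
  std::vector<int> stack;
  for (int q = 0; q < nq; ++q) {
    V3 p(query(q, 0), query(q, 1), query(q, 2));
    double best = R_PosInf;
    V3 bestq; int bestf = -1;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back(); stack.pop_back();
      const BVHNode& nd = bvh.nodes[ni];
      if (box_dist2(nd, p) >= best * best) continue;
      if (nd.left < 0) {
        for (int t = nd.begin; t < nd.end; ++t) {
          int f = bvh.order[t];
          int i0 = tri(f, 0) - 1, i1 = tri(f, 1) - 1, i2 = tri(f, 2) - 1;
          V3 a(pos(i0, 0), pos(i0, 1), pos(i0, 2));
          V3 b(pos(i1, 0), pos(i1, 1), pos(i1, 2));
          V3 c(pos(i2, 0), pos(i2, 1), pos(i2, 2));
          V3 cp = closest_point_triangle(p, a, b, c);
          double d = norm(p - cp);
          if (d < best || (d == best && f < bestf)) {
            best = d; bestq = cp; bestf = f;
          }
        }
      } else {
        // visit nearer child last so it is popped first
        double dl = box_dist2(bvh.nodes[nd.left], p);
        double dr = box_dist2(bvh.nodes[nd.right], p);
        if (dl < dr) { stack.push_back(nd.right); stack.push_back(nd.left); }
        else { stack.push_back(nd.left); stack.push_back(nd.right); }
      }
    }
    dist[q] = best;
    closest(q, 0) = bestq.x; closest(q, 1) = bestq.y; closest(q, 2) = bestq.z;
    tri_id[q] = bestf + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["triangle"] = tri_id);
}

// ---------------------------------------------------------------------------
// vertex normals and lumped areas
// ---------------------------------------------------------------------------

static void normals_areas(const std::vector<V3>& p, const IntegerMatrix& tri,
                          std::vector<V3>& vnorm, std::vector<double>& varea,
                          double* total_area) {
  int n = (int)p.size(), m = tri.nrow();
  vnorm.assign(n, V3());
  varea.assign(n, 0.0);
  double tot = 0;
  for (int f = 0; f < m; ++f) {
    int i = tri(f, 0) - 1, j = tri(f, 1) - 1, k = tri(f, 2) - 1;
    V3 N = cross(p[j] - p[i], p[k] - p[i]);   // |N| = 2 * area
    double A = 0.5 * norm(N);
    tot += A;
    double third = A / 3.0;
    vnorm[i] = vnorm[i] + N; vnorm[j] = vnorm[j] + N; vnorm[k] = vnorm[k] + N;
    varea[i] += third; varea[j] += third; varea[k] += third;
  }
  for (int v = 0; v < n; ++v) {
    double l = norm(vnorm[v]);
    if (l > 0) vnorm[v] = (1.0 / l) * vnorm[v];
  }
  if (total_area) *total_area = tot;
}

// [[Rcpp::export]]
List cpp_vertex_normals_areas(NumericMatrix pos, IntegerMatrix tri) {
  int n = pos.nrow();
  std::vector<V3> p(n);
  for (int v = 0; v < n; ++v) p[v] = V3(pos(v, 0), pos(v, 1), pos(v, 2));
  std::vector<V3> vn; std::vector<double> va;
  double tot;
  normals_areas(p, tri, vn, va, &tot);
  NumericMatrix normals(n, 3);
  NumericVector areas(n);
  for (int v = 0; v < n; ++v) {
    if (va[v] > 0 && norm(vn[v]) == 0)
      stop("vertex_normals: zero-length normal at vertex %d", v + 1);
    normals(v, 0) = vn[v].x; normals(v, 1) = vn[v].y; normals(v, 2) = vn[v].z;
    areas[v] = va[v];
  }
  return List::create(_["normals"] = normals, _["areas"] = areas,
                      _["total_area"] = tot);
}

// ---------------------------------------------------------------------------
// collision detection: vertex vs non-incident triangle within thickness h,
// uniform spatial hash over vertices (cell size >= h)
// ---------------------------------------------------------------------------

struct Contact { int v, f; };

static void detect_contacts(const std::vector<V3>& p, const IntegerMatrix& tri,
                            double h, std::vector<Contact>& out) {
  out.clear();
  int n = (int)p.size(), m = tri.nrow();
  // cell size >= h; matching the typical triangle extent keeps the number of
  // cells a triangle's padded AABB overlaps small
  double mean_ext = 0;
  for (int f = 0; f < m; ++f) {
    int i0 = tri(f, 0) - 1, i1 = tri(f, 1) - 1, i2 = tri(f, 2) - 1;
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double c0 = k == 0 ? p[i0].x : (k == 1 ? p[i0].y : p[i0].z);
      double c1 = k == 0 ? p[i1].x : (k == 1 ? p[i1].y : p[i1].z);
      double c2 = k == 0 ? p[i2].x : (k == 1 ? p[i2].y : p[i2].z);
      lo[k] = std::min({c0, c1, c2}); hi[k] = std::max({c0, c1, c2});
    }
    mean_ext += std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]});
  }
  if (m > 0) mean_ext /= m;
  double cell = std::max({h, mean_ext, 1e-6});
  auto key = [cell](double x, double y, double z) -> std::int64_t {
    std::int64_t ix = (std::int64_t)std::floor(x / cell);
    std::int64_t iy = (std::int64_t)std::floor(y / cell);
    std::int64_t iz = (std::int64_t)std::floor(z / cell);
    return ((ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL));
  };
  std::unordered_map<std::int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  for (int v = 0; v < n; ++v)
    grid[key(p[v].x, p[v].y, p[v].z)].push_back(v);  // ascending v per cell

  for (int f = 0; f < m; ++f) {
    int i0 = tri(f, 0) - 1, i1 = tri(f, 1) - 1, i2 = tri(f, 2) - 1;
    const V3 &a = p[i0], &b = p[i1], &c = p[i2];
    double lo[3] = { std::min({a.x, b.x, c.x}) - h, std::min({a.y, b.y, c.y}) - h,
                     std::min({a.z, b.z, c.z}) - h };
    double hi[3] = { std::max({a.x, b.x, c.x}) + h, std::max({a.y, b.y, c.y}) + h,
                     std::max({a.z, b.z, c.z}) + h };
    std::int64_t x0 = (std::int64_t)std::floor(lo[0] / cell), x1 = (std::int64_t)std::floor(hi[0] / cell);
    std::int64_t y0 = (std::int64_t)std::floor(lo[1] / cell), y1 = (std::int64_t)std::floor(hi[1] / cell);
    std::int64_t z0 = (std::int64_t)std::floor(lo[2] / cell), z1 = (std::int64_t)std::floor(hi[2] / cell);
    for (std::int64_t ix = x0; ix <= x1; ++ix)
      for (std::int64_t iy = y0; iy <= y1; ++iy)
        for (std::int64_t iz = z0; iz <= z1; ++iz) {
          auto it = grid.find((ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL));
          if (it == grid.end()) continue;
          for (int v : it->second) {
            if (v == i0 || v == i1 || v == i2) continue;
            const V3& q = p[v];
            if (q.x < lo[0] || q.x > hi[0] || q.y < lo[1] || q.y > hi[1] ||
                q.z < lo[2] || q.z > hi[2]) continue;  // hash bucket collision guard
            V3 cp = closest_point_triangle(q, a, b, c);
            if (norm(q - cp) < h) out.push_back({v, f});
          }
        }
  }
  // deterministic order independent of hash iteration: sort by (triangle, vertex)
  std::sort(out.begin(), out.end(), [](const Contact& u, const Contact& w) {
    if (u.f != w.f) return u.f < w.f;
    return u.v < w.v;
  });
  out.erase(std::unique(out.begin(), out.end(), [](const Contact& u, const Contact& w) {
    return u.f == w.f && u.v == w.v;
  }), out.end());
}

// Reorder contacts so that mirror-image pairs are adjacent (mirror_v /
// mirror_f are 0-based vertex/triangle mirror permutations). Paired
// one-sided contacts touch disjoint vertex sets on a plane-free mesh, so
// adjacent processing keeps a Gauss-Seidel sweep mirror-equivariant.
static void pair_order_contacts(std::vector<Contact>& out, int nverts,
                                const std::vector<int>& mirror_v,
                                const std::vector<int>& mirror_f,
                                std::vector<int>& pair_start) {
  struct Key { double canon; int second; int f, v; };
  std::vector<Key> keys(out.size());
  for (size_t k = 0; k < out.size(); ++k) {
    double k1 = (double)out[k].f * nverts + out[k].v;
    double k2 = (double)mirror_f[out[k].f] * nverts + mirror_v[out[k].v];
    keys[k] = { std::min(k1, k2), k1 > k2 ? 1 : 0, out[k].f, out[k].v };
  }
  std::sort(keys.begin(), keys.end(), [](const Key& a, const Key& b) {
    if (a.canon != b.canon) return a.canon < b.canon;
    return a.second < b.second;
  });
  pair_start.assign(out.size(), 0);
  for (size_t k = 0; k < out.size(); ++k) out[k] = { keys[k].v, keys[k].f };
  for (size_t k = 0; k + 1 < out.size(); ++k)
    if (keys[k].canon == keys[k + 1].canon && keys[k].second == 0 &&
        keys[k + 1].second == 1)
      pair_start[k] = 1;
}

// [[Rcpp::export]]
IntegerMatrix cpp_detect_collisions(NumericMatrix pos, IntegerMatrix tri, double h) {
  int n = pos.nrow();
  std::vector<V3> p(n);
  for (int v = 0; v < n; ++v) p[v] = V3(pos(v, 0), pos(v, 1), pos(v, 2));
  std::vector<Contact> out;
  detect_contacts(p, tri, h, out);
  IntegerMatrix res((int)out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res((int)k, 0) = out[k].v + 1;   // vertex (1-based)
    res((int)k, 1) = out[k].f + 1;   // triangle (1-based)
  }
  colnames(res) = CharacterVector::create("vertex", "triangle");
  return res;
}

// ---------------------------------------------------------------------------
// XPBD constraint projections (shared by the solver loop and the R wrappers)
// ---------------------------------------------------------------------------

// The projection kernels compute position *deltas* without mutating the
// input state. The solver applies a mirror pair of constraints from the same
// state and adds both deltas afterwards: for vertex-disjoint pairs this is
// bit-identical to sequential Gauss-Seidel, and for pairs sharing an
// on-symmetry-plane vertex it keeps the sweep exactly mirror-equivariant.

// Equality distance constraint C = |pi - pj| - l0.
static void project_distance(const V3& pi, const V3& pj, double wi, double wj,
                             double l0, double alpha, double dt, double& lambda,
                             V3& dpi, V3& dpj) {
  dpi = V3(); dpj = V3();
  V3 d = pi - pj;
  double len = norm(d);
  if (len < 1e-12) return;                 // degenerate: no defined direction
  double C = len - l0;
  double at = alpha / (dt * dt);
  double denom = wi + wj + at;
  if (denom <= 0) return;
  double dl = (-C - at * lambda) / denom;
  lambda += dl;
  V3 nrm = (1.0 / len) * d;
  dpi = (wi * dl) * nrm;
  dpj = V3() - (wj * dl) * nrm;
}

// One-sided cord constraint: active only when stretched (|pj - tip| - l0 >= 0,
// weight k^CT = 1); slack cords (k^CT = 0) leave the vertex untouched.
// The tip is a Dirichlet anchor (w = 0) and never moves.
static void project_cord(const V3& tip, const V3& pj, double wj,
                         double l0, double alpha, double dt, double& lambda,
                         V3& dpj) {
  dpj = V3();
  V3 d = pj - tip;
  double len = norm(d);
  double C = len - l0;
  if (C < 0) return;                       // compression: k^CT = 0
  if (len < 1e-12) return;
  double at = alpha / (dt * dt);
  double denom = wj + at;
  if (denom <= 0) return;
  double dl = (-C - at * lambda) / denom;
  double lnew = lambda + dl;
  if (lnew > 0) lnew = 0;                  // inequality multiplier: pull only
  dl = lnew - lambda;
  lambda = lnew;
  dpj = (wj * dl) * ((1.0 / len) * d);
}

// Area constraint C = area - A0.
static void project_area(const V3& p1, const V3& p2, const V3& p3,
                         double w1, double w2, double w3,
                         double a0, double alpha, double dt, double& lambda,
                         V3& dp1, V3& dp2, V3& dp3) {
  dp1 = V3(); dp2 = V3(); dp3 = V3();
  V3 u = p2 - p1, v = p3 - p1;
  V3 N = cross(u, v);
  double twoA = norm(N);
  if (twoA < 1e-12) return;
  V3 n = (1.0 / twoA) * N;
  double C = 0.5 * twoA - a0;
  V3 g2 = 0.5 * cross(v, n);
  V3 g3 = 0.5 * cross(n, u);
  V3 g1 = V3() - (g2 + g3);
  double at = alpha / (dt * dt);
  double denom = w1 * dot(g1, g1) + w2 * dot(g2, g2) + w3 * dot(g3, g3) + at;
  if (denom <= 1e-15) return;
  double dl = (-C - at * lambda) / denom;
  lambda += dl;
  dp1 = (w1 * dl) * g1;
  dp2 = (w2 * dl) * g2;
  dp3 = (w3 * dl) * g3;
}

// Dihedral angle of triangles (p1,p3,p2) and (p1,p2,p4) sharing edge p1-p2;
// flat (coplanar, opposite sides) gives pi.
static double dihedral_angle(const V3& p1, const V3& p2, const V3& p3, const V3& p4) {
  V3 e = p2 - p1, u = p3 - p1, v = p4 - p1;
  V3 N1 = cross(e, u), N2 = cross(e, v);
  double l1 = norm(N1), l2 = norm(N2);
  if (l1 < 1e-12 || l2 < 1e-12) return NA_REAL;
  double d = dot(N1, N2) / (l1 * l2);
  if (d > 1) d = 1; if (d < -1) d = -1;
  // normals of consistently wound neighbours face "together" when folded;
  // the angle between surface normals complements the dihedral
  return M_PI - std::acos(-d);
}

// Bending constraint C = phi - phi0 on the dihedral angle; analytic gradients
// via the chain rule through both face normals.
static void project_bending(const V3& p1, const V3& p2, const V3& p3, const V3& p4,
                            double w1, double w2, double w3, double w4,
                            double phi0, double alpha, double dt, double& lambda,
                            V3& dp1, V3& dp2, V3& dp3, V3& dp4) {
  dp1 = V3(); dp2 = V3(); dp3 = V3(); dp4 = V3();
  V3 e = p2 - p1, u = p3 - p1, v = p4 - p1;
  V3 N1 = cross(e, u), N2 = cross(e, v);
  double l1 = norm(N1), l2 = norm(N2);
  if (l1 < 1e-12 || l2 < 1e-12) return;
  V3 n1 = (1.0 / l1) * N1, n2 = (1.0 / l2) * N2;
  double d = dot(n1, n2);
  if (d > 1) d = 1; if (d < -1) d = -1;
  double s = std::sqrt(1.0 - d * d);
  if (s < 1e-9) return;                     // flat/folded flat: gradient undefined
  double phi = M_PI - std::acos(-d);        // == acos(d) complement form
  double C = phi - phi0;
  // phi = pi - acos(-d)  =>  dphi/dd = -1/sqrt(1-d^2)
  double dphi_dd = -1.0 / s;
  // dd/dN1 = (n2 - d*n1)/l1 ; dd/dN2 = (n1 - d*n2)/l2
  V3 gN1 = (1.0 / l1) * (n2 - d * n1);
  V3 gN2 = (1.0 / l2) * (n1 - d * n2);
  // N1 = e x u, N2 = e x v; transfer: g_a = b x g_N for N = a x b
  V3 ge = cross(u, gN1) + cross(v, gN2);
  V3 gu = cross(gN1, e);
  V3 gv = cross(gN2, e);
  V3 g2 = dphi_dd * ge;
  V3 g3 = dphi_dd * gu;
  V3 g4 = dphi_dd * gv;
  V3 g1 = V3() - (g2 + g3 + g4);
  double at = alpha / (dt * dt);
  double denom = w1 * dot(g1, g1) + w2 * dot(g2, g2) +
                 w3 * dot(g3, g3) + w4 * dot(g4, g4) + at;
  if (denom <= 1e-15) return;
  double dl = (-C - at * lambda) / denom;
  lambda += dl;
  dp1 = (w1 * dl) * g1;
  dp2 = (w2 * dl) * g2;
  dp3 = (w3 * dl) * g3;
  dp4 = (w4 * dl) * g4;
}

// One-sided vertex-triangle contact: C = dist - h >= 0, rigid (alpha = 0).
static void project_contact(const V3& q, const V3& a, const V3& b, const V3& c,
                            double wq, double wa, double wb, double wc,
                            double h, double& lambda,
                            V3& dq, V3& da, V3& db, V3& dc) {
  dq = V3(); da = V3(); db = V3(); dc = V3();
  double bary[3];
  V3 cp = closest_point_triangle(q, a, b, c, bary);
  V3 d = q - cp;
  double len = norm(d);
  if (len < 1e-12) return;                  // exactly on the surface: skip
  double C = len - h;
  double denom = wq + wa * bary[0] * bary[0] + wb * bary[1] * bary[1] +
                 wc * bary[2] * bary[2];
  if (denom <= 0) return;
  double dl = (-C) / denom;
  double lnew = lambda + dl;
  if (lnew < 0) lnew = 0;                   // push apart only
  dl = lnew - lambda;
  lambda = lnew;
  V3 nrm = (1.0 / len) * d;
  dq = (wq * dl) * nrm;
  da = V3() - (wa * bary[0] * dl) * nrm;
  db = V3() - (wb * bary[1] * dl) * nrm;
  dc = V3() - (wc * bary[2] * dl) * nrm;
}

// --- single-constraint R wrappers (unit-test surface) ----------------------

// [[Rcpp::export]]
List cpp_project_distance(NumericMatrix P, NumericVector w, double l0,
                          double alpha, double dt, double lambda) {
  V3 pi(P(0, 0), P(0, 1), P(0, 2)), pj(P(1, 0), P(1, 1), P(1, 2));
  V3 di, dj;
  project_distance(pi, pj, w[0], w[1], l0, alpha, dt, lambda, di, dj);
  pi = pi + di; pj = pj + dj;
  NumericMatrix out(2, 3);
  out(0, 0) = pi.x; out(0, 1) = pi.y; out(0, 2) = pi.z;
  out(1, 0) = pj.x; out(1, 1) = pj.y; out(1, 2) = pj.z;
  return List::create(_["positions"] = out, _["lambda"] = lambda);
}

// [[Rcpp::export]]
List cpp_project_cord(NumericVector tip, NumericVector pj, double wj, double l0,
                      double alpha, double dt, double lambda) {
  V3 t(tip[0], tip[1], tip[2]), p(pj[0], pj[1], pj[2]);
  V3 dp;
  project_cord(t, p, wj, l0, alpha, dt, lambda, dp);
  p = p + dp;
  return List::create(_["position"] = NumericVector::create(p.x, p.y, p.z),
                      _["lambda"] = lambda);
}

// [[Rcpp::export]]
List cpp_project_area(NumericMatrix P, NumericVector w, double a0,
                      double alpha, double dt, double lambda) {
  V3 p1(P(0, 0), P(0, 1), P(0, 2)), p2(P(1, 0), P(1, 1), P(1, 2)), p3(P(2, 0), P(2, 1), P(2, 2));
  V3 d1, d2, d3;
  project_area(p1, p2, p3, w[0], w[1], w[2], a0, alpha, dt, lambda, d1, d2, d3);
  p1 = p1 + d1; p2 = p2 + d2; p3 = p3 + d3;
  NumericMatrix out(3, 3);
  out(0, 0) = p1.x; out(0, 1) = p1.y; out(0, 2) = p1.z;
  out(1, 0) = p2.x; out(1, 1) = p2.y; out(1, 2) = p2.z;
  out(2, 0) = p3.x; out(2, 1) = p3.y; out(2, 2) = p3.z;
  return List::create(_["positions"] = out, _["lambda"] = lambda);
}

// [[Rcpp::export]]
double cpp_dihedral_angle(NumericMatrix P) {
  return dihedral_angle(V3(P(0, 0), P(0, 1), P(0, 2)), V3(P(1, 0), P(1, 1), P(1, 2)),
                        V3(P(2, 0), P(2, 1), P(2, 2)), V3(P(3, 0), P(3, 1), P(3, 2)));
}

// [[Rcpp::export]]
List cpp_project_bending(NumericMatrix P, NumericVector w, double phi0,
                         double alpha, double dt, double lambda) {
  V3 p1(P(0, 0), P(0, 1), P(0, 2)), p2(P(1, 0), P(1, 1), P(1, 2));
  V3 p3(P(2, 0), P(2, 1), P(2, 2)), p4(P(3, 0), P(3, 1), P(3, 2));
  V3 d1, d2, d3, d4;
  project_bending(p1, p2, p3, p4, w[0], w[1], w[2], w[3], phi0, alpha, dt, lambda,
                  d1, d2, d3, d4);
  p1 = p1 + d1; p2 = p2 + d2; p3 = p3 + d3; p4 = p4 + d4;
  NumericMatrix out(4, 3);
  out(0, 0) = p1.x; out(0, 1) = p1.y; out(0, 2) = p1.z;
  out(1, 0) = p2.x; out(1, 1) = p2.y; out(1, 2) = p2.z;
  out(2, 0) = p3.x; out(2, 1) = p3.y; out(2, 2) = p3.z;
  out(3, 0) = p4.x; out(3, 1) = p4.y; out(3, 2) = p4.z;
  return List::create(_["positions"] = out, _["lambda"] = lambda);
}

// [[Rcpp::export]]
List cpp_project_collision(NumericVector q, NumericMatrix T, NumericVector w,
                           double h, double lambda) {
  V3 p(q[0], q[1], q[2]);
  V3 a(T(0, 0), T(0, 1), T(0, 2)), b(T(1, 0), T(1, 1), T(1, 2)), c(T(2, 0), T(2, 1), T(2, 2));
  V3 dq, da, db, dc;
  project_contact(p, a, b, c, w[0], w[1], w[2], w[3], h, lambda, dq, da, db, dc);
  p = p + dq; a = a + da; b = b + db; c = c + dc;
  NumericMatrix out(4, 3);
  out(0, 0) = p.x; out(0, 1) = p.y; out(0, 2) = p.z;
  out(1, 0) = a.x; out(1, 1) = a.y; out(1, 2) = a.z;
  out(2, 0) = b.x; out(2, 1) = b.y; out(2, 2) = b.z;
  out(3, 0) = c.x; out(3, 1) = c.y; out(3, 2) = c.z;
  return List::create(_["positions"] = out, _["lambda"] = lambda);
}

// ---------------------------------------------------------------------------
// the time-stepping loop
// ---------------------------------------------------------------------------

static inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// [[Rcpp::export]]
List cpp_xpbd_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector inv_mass,
                  double t0, IntegerMatrix tri,
                  IntegerMatrix dist_ij, NumericVector dist_l0, NumericVector dist_alpha,
                  IntegerMatrix bend_ijkl, NumericVector bend_phi0, NumericVector bend_alpha,
                  IntegerMatrix area_ijk, NumericVector area_a0, NumericVector area_alpha,
                  IntegerVector cord_tip, IntegerVector cord_vertex,
                  NumericVector cord_l0, NumericVector cord_alpha,
                  NumericMatrix tips_open, NumericMatrix tips_closed,
                  IntegerVector annulus_ids, NumericMatrix ann_open, NumericMatrix ann_closed,
                  double close_duration,
                  double phase_sign, double pressure, double gamma_drag,
                  double target_speed, NumericVector ap_normal,
                  double dt, int substeps, int iterations, double damping,
                  double h_contact,
                  int n_steps, double steady_tol, int steady_window,
                  IntegerVector mirror_vertex, IntegerVector mirror_triangle,
                  IntegerVector dist_pair, IntegerVector bend_pair,
                  IntegerVector area_pair, IntegerVector cord_pair) {
  const int n = pos0.nrow();
  std::vector<V3> p(n), v(n), p_prev(n), p_step(n);
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) {
    p[i] = V3(pos0(i, 0), pos0(i, 1), pos0(i, 2));
    v[i] = V3(vel0(i, 0), vel0(i, 1), vel0(i, 2));
    w[i] = inv_mass[i];
  }
  const int nd = dist_ij.nrow(), nb = bend_ijkl.nrow(), na = area_ijk.nrow(),
            nc = cord_vertex.size(), nann = annulus_ids.size();
  std::vector<double> lam_d(nd), lam_b(nb), lam_a(na), lam_c(nc);
  std::vector<double> lam_col;
  std::vector<Contact> contacts;
  std::vector<int> contact_pair;
  std::vector<V3> vnorm; std::vector<double> varea;
  V3 nap(ap_normal[0], ap_normal[1], ap_normal[2]);
  const bool paired = mirror_vertex.size() == n &&
                      mirror_triangle.size() == tri.nrow();
  std::vector<int> mv, mf;
  if (paired) {
    mv.resize(n); mf.resize(tri.nrow());
    for (int i = 0; i < n; ++i) mv[i] = mirror_vertex[i] - 1;
    for (int f = 0; f < tri.nrow(); ++f) mf[f] = mirror_triangle[f] - 1;
  }
  double t = t0;
  const double dts = dt / substeps;

  NumericMatrix log(n_steps, 5);   // step, time, max_disp, area, contacts
  int steps_done = 0;
  bool converged = false;
  int steady_run = 0;

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) p_step[i] = p[i];
    int ncontacts_last = 0;
    for (int sub = 0; sub < substeps; ++sub) {
      double t_new = t + dts;
      for (int i = 0; i < n; ++i) p_prev[i] = p[i];

      // (1) Dirichlet targets at the end of the substep
      double s = close_duration > 0 ? clamp01(t_new / close_duration) : 1.0;
      for (int k = 0; k < nann; ++k) {
        int id = annulus_ids[k] - 1;
        p[id] = V3((1 - s) * ann_open(k, 0) + s * ann_closed(k, 0),
                   (1 - s) * ann_open(k, 1) + s * ann_closed(k, 1),
                   (1 - s) * ann_open(k, 2) + s * ann_closed(k, 2));
        if (s == 0.0) p[id] = V3(ann_open(k, 0), ann_open(k, 1), ann_open(k, 2));
        if (s == 1.0) p[id] = V3(ann_closed(k, 0), ann_closed(k, 1), ann_closed(k, 2));
      }
      V3 tip_pos[2];
      for (int k = 0; k < 2; ++k) {
        tip_pos[k] = V3((1 - s) * tips_open(k, 0) + s * tips_closed(k, 0),
                        (1 - s) * tips_open(k, 1) + s * tips_closed(k, 1),
                        (1 - s) * tips_open(k, 2) + s * tips_closed(k, 2));
      }

      // (2) external forces + semi-implicit Euler predictor
      normals_areas(p, tri, vnorm, varea, nullptr);
      for (int i = 0; i < n; ++i) {
        if (w[i] <= 0) continue;
        double m = 1.0 / w[i];
        V3 f = (phase_sign * pressure * varea[i]) * vnorm[i];
        V3 vtarget = (-phase_sign * target_speed) * nap;
        f = f + (gamma_drag * m) * (vtarget - v[i]);
        v[i] = v[i] + (dts * w[i]) * f;
        p[i] = p[i] + dts * v[i];
      }

      // (3) collision detection + Gauss-Seidel sweeps, lambdas reset
      detect_contacts(p, tri, h_contact, contacts);
      if (paired) pair_order_contacts(contacts, n, mv, mf, contact_pair);
      else contact_pair.assign(contacts.size(), 0);
      ncontacts_last = (int)contacts.size();
      std::fill(lam_d.begin(), lam_d.end(), 0.0);
      std::fill(lam_b.begin(), lam_b.end(), 0.0);
      std::fill(lam_a.begin(), lam_a.end(), 0.0);
      std::fill(lam_c.begin(), lam_c.end(), 0.0);
      lam_col.assign(contacts.size(), 0.0);
      for (int it = 0; it < iterations; ++it) {
        // each mirror pair is projected from the same state and both deltas
        // applied together: identical to sequential Gauss-Seidel for
        // vertex-disjoint pairs, exactly mirror-equivariant otherwise
        for (int k = 0; k < nd; ++k) {
          int i = dist_ij(k, 0) - 1, j = dist_ij(k, 1) - 1;
          V3 di, dj;
          project_distance(p[i], p[j], w[i], w[j], dist_l0[k], dist_alpha[k],
                           dts, lam_d[k], di, dj);
          if (dist_pair.size() == nd && dist_pair[k] == 1 && k + 1 < nd) {
            int i2 = dist_ij(k + 1, 0) - 1, j2 = dist_ij(k + 1, 1) - 1;
            V3 di2, dj2;
            project_distance(p[i2], p[j2], w[i2], w[j2], dist_l0[k + 1],
                             dist_alpha[k + 1], dts, lam_d[k + 1], di2, dj2);
            p[i] = p[i] + di; p[j] = p[j] + dj;
            p[i2] = p[i2] + di2; p[j2] = p[j2] + dj2;
            ++k;
          } else {
            p[i] = p[i] + di; p[j] = p[j] + dj;
          }
        }
        for (int k = 0; k < nb; ++k) {
          int i1 = bend_ijkl(k, 0) - 1, i2 = bend_ijkl(k, 1) - 1,
              i3 = bend_ijkl(k, 2) - 1, i4 = bend_ijkl(k, 3) - 1;
          V3 d1, d2, d3, d4;
          project_bending(p[i1], p[i2], p[i3], p[i4], w[i1], w[i2], w[i3], w[i4],
                          bend_phi0[k], bend_alpha[k], dts, lam_b[k],
                          d1, d2, d3, d4);
          if (bend_pair.size() == nb && bend_pair[k] == 1 && k + 1 < nb) {
            int j1 = bend_ijkl(k + 1, 0) - 1, j2 = bend_ijkl(k + 1, 1) - 1,
                j3 = bend_ijkl(k + 1, 2) - 1, j4 = bend_ijkl(k + 1, 3) - 1;
            V3 e1, e2, e3, e4;
            project_bending(p[j1], p[j2], p[j3], p[j4], w[j1], w[j2], w[j3], w[j4],
                            bend_phi0[k + 1], bend_alpha[k + 1], dts, lam_b[k + 1],
                            e1, e2, e3, e4);
            p[i1] = p[i1] + d1; p[i2] = p[i2] + d2; p[i3] = p[i3] + d3; p[i4] = p[i4] + d4;
            p[j1] = p[j1] + e1; p[j2] = p[j2] + e2; p[j3] = p[j3] + e3; p[j4] = p[j4] + e4;
            ++k;
          } else {
            p[i1] = p[i1] + d1; p[i2] = p[i2] + d2; p[i3] = p[i3] + d3; p[i4] = p[i4] + d4;
          }
        }
        for (int k = 0; k < na; ++k) {
          int i1 = area_ijk(k, 0) - 1, i2 = area_ijk(k, 1) - 1, i3 = area_ijk(k, 2) - 1;
          V3 d1, d2, d3;
          project_area(p[i1], p[i2], p[i3], w[i1], w[i2], w[i3],
                       area_a0[k], area_alpha[k], dts, lam_a[k], d1, d2, d3);
          if (area_pair.size() == na && area_pair[k] == 1 && k + 1 < na) {
            int j1 = area_ijk(k + 1, 0) - 1, j2 = area_ijk(k + 1, 1) - 1,
                j3 = area_ijk(k + 1, 2) - 1;
            V3 e1, e2, e3;
            project_area(p[j1], p[j2], p[j3], w[j1], w[j2], w[j3],
                         area_a0[k + 1], area_alpha[k + 1], dts, lam_a[k + 1],
                         e1, e2, e3);
            p[i1] = p[i1] + d1; p[i2] = p[i2] + d2; p[i3] = p[i3] + d3;
            p[j1] = p[j1] + e1; p[j2] = p[j2] + e2; p[j3] = p[j3] + e3;
            ++k;
          } else {
            p[i1] = p[i1] + d1; p[i2] = p[i2] + d2; p[i3] = p[i3] + d3;
          }
        }
        for (int k = 0; k < nc; ++k) {
          int j = cord_vertex[k] - 1;
          V3 dp;
          project_cord(tip_pos[cord_tip[k] - 1], p[j], w[j],
                       cord_l0[k], cord_alpha[k], dts, lam_c[k], dp);
          if (cord_pair.size() == nc && cord_pair[k] == 1 && k + 1 < nc) {
            int j2 = cord_vertex[k + 1] - 1;
            V3 dp2;
            project_cord(tip_pos[cord_tip[k + 1] - 1], p[j2], w[j2],
                         cord_l0[k + 1], cord_alpha[k + 1], dts, lam_c[k + 1], dp2);
            p[j] = p[j] + dp;
            p[j2] = p[j2] + dp2;
            ++k;
          } else {
            p[j] = p[j] + dp;
          }
        }
        for (size_t k = 0; k < contacts.size(); ++k) {
          int q = contacts[k].v, f = contacts[k].f;
          int a = tri(f, 0) - 1, b = tri(f, 1) - 1, c = tri(f, 2) - 1;
          V3 dq, da, db, dc;
          project_contact(p[q], p[a], p[b], p[c], w[q], w[a], w[b], w[c],
                          h_contact, lam_col[k], dq, da, db, dc);
          if (contact_pair[k] == 1 && k + 1 < contacts.size()) {
            int q2 = contacts[k + 1].v, f2 = contacts[k + 1].f;
            int a2 = tri(f2, 0) - 1, b2 = tri(f2, 1) - 1, c2 = tri(f2, 2) - 1;
            V3 dq2, da2, db2, dc2;
            project_contact(p[q2], p[a2], p[b2], p[c2], w[q2], w[a2], w[b2], w[c2],
                            h_contact, lam_col[k + 1], dq2, da2, db2, dc2);
            p[q] = p[q] + dq; p[a] = p[a] + da; p[b] = p[b] + db; p[c] = p[c] + dc;
            p[q2] = p[q2] + dq2; p[a2] = p[a2] + da2; p[b2] = p[b2] + db2; p[c2] = p[c2] + dc2;
            ++k;
          } else {
            p[q] = p[q] + dq; p[a] = p[a] + da; p[b] = p[b] + db; p[c] = p[c] + dc;
          }
        }
      }

      // (4) velocity update; `damping` is the per-step loss, spread evenly
      // over the substeps
      double inv_dts = 1.0 / dts;
      double keep = std::pow(1.0 - damping, 1.0 / substeps);
      for (int i = 0; i < n; ++i) {
        v[i] = (keep * inv_dts) * (p[i] - p_prev[i]);
        if (!std::isfinite(p[i].x) || !std::isfinite(p[i].y) || !std::isfinite(p[i].z))
          stop("solver diverged at t = %g (step %d): non-finite position at vertex %d",
               t_new, step + 1, i + 1);
      }
      t = t_new;
    }

    double max_disp = 0;
    for (int i = 0; i < n; ++i) {
      double d = norm(p[i] - p_step[i]);
      if (d > max_disp) max_disp = d;
    }
    double area_now;
    normals_areas(p, tri, vnorm, varea, &area_now);
    log(step, 0) = step + 1;
    log(step, 1) = t;
    log(step, 2) = max_disp;
    log(step, 3) = area_now;
    log(step, 4) = ncontacts_last;
    steps_done = step + 1;

    if (steady_window > 0) {
      steady_run = (max_disp < steady_tol) ? steady_run + 1 : 0;
      if (steady_run >= steady_window) { converged = true; break; }
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = p[i].x; pos_out(i, 1) = p[i].y; pos_out(i, 2) = p[i].z;
    vel_out(i, 0) = v[i].x; vel_out(i, 1) = v[i].y; vel_out(i, 2) = v[i].z;
  }
  return List::create(_["pos"] = pos_out, _["vel"] = vel_out, _["t"] = t,
                      _["steps"] = steps_done, _["converged"] = converged,
                      _["log"] = log(Range(0, std::max(steps_done - 1, 0)), _));
}
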