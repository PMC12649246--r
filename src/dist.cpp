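// Nearest point-to-triangle queries over a triangle mesh, accelerated by an
// axis-aligned bounding-box hierarchy (median split, leaf size 8), plus
// angle-weighted pseudonormals for robust inside/outside classification of
// near-surface query points on closed meshes.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <map>
using namespace Rcpp;

namespace {

struct Vec {
  double x, y, z;
  Vec() : x(0), y(0), z(0) {}
  Vec(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec operator-(const Vec &o) const { return Vec(x - o.x, y - o.y, z - o.z); }
  Vec operator+(const Vec &o) const { return Vec(x + o.x, y + o.y, z + o.z); }
  Vec operator*(double s) const { return Vec(x * s, y * s, z * s); }
};
inline double dot(const Vec &a, const Vec &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec cross(const Vec &a, const Vec &b) {
  return Vec(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec &a) { return std::sqrt(dot(a, a)); }

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p,
// with barycentric output (u,v,w) wrt (a,b,c).
Vec closest_point_triangle(const Vec &p, const Vec &a, const Vec &b,
                           const Vec &c, double bary[3]) {
  const Vec ab = b - a, ac = c - a, ap = p - a;
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { bary[0] = 1; bary[1] = 0; bary[2] = 0; return a; }
  const Vec bp = p - b;
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { bary[0] = 0; bary[1] = 1; bary[2] = 0; return b; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    const double v = d1 / (d1 - d3);
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return a + ab * v;
  }
  const Vec cp = p - c;
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { bary[0] = 0; bary[1] = 0; bary[2] = 1; return c; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    const double w = d2 / (d2 - d6);
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return a + ac * w;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return b + (c - b) * w;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
  return a + ab * v + ac * w;
}

struct Node {
  double lo[3], hi[3];
  int left, right;   // children, or -1
  int start, count;  // leaf triangle range in order[]
};

struct BVH {
  std::vector<Vec> V;
  std::vector<int> F0, F1, F2;
  std::vector<Node> nodes;
  std::vector<int> order;
  std::vector<Vec> centroid;

  void tri_bounds(int t, double lo[3], double hi[3]) const {
    const Vec &a = V[F0[t]], &b = V[F1[t]], &c = V[F2[t]];
    lo[0] = std::min(a.x, std::min(b.x, c.x));
    lo[1] = std::min(a.y, std::min(b.y, c.y));
    lo[2] = std::min(a.z, std::min(b.z, c.z));
    hi[0] = std::max(a.x, std::max(b.x, c.x));
    hi[1] = std::max(a.y, std::max(b.y, c.y));
    hi[2] = std::max(a.z, std::max(b.z, c.z));
  }

  int build(int start, int count) {
    Node nd;
    nd.lo[0] = nd.lo[1] = nd.lo[2] = R_PosInf;
    nd.hi[0] = nd.hi[1] = nd.hi[2] = R_NegInf;
    for (int i = start; i < start + count; ++i) {
      double lo[3], hi[3];
      tri_bounds(order[i], lo, hi);
      for (int a = 0; a < 3; ++a) {
        nd.lo[a] = std::min(nd.lo[a], lo[a]);
        nd.hi[a] = std::max(nd.hi[a], hi[a]);
      }
    }
    const int self = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 8) {
      nodes[self].left = nodes[self].right = -1;
      nodes[self].start = start; nodes[self].count = count;
      return self;
    }
    int axis = 0;
    double ext = nd.hi[0] - nd.lo[0];
    for (int a = 1; a < 3; ++a)
      if (nd.hi[a] - nd.lo[a] > ext) { ext = nd.hi[a] - nd.lo[a]; axis = a; }
    const int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int a, int b) {
                       const Vec &ca = centroid[a], &cb = centroid[b];
                       const double va = axis == 0 ? ca.x : (axis == 1 ? ca.y : ca.z);
                       const double vb = axis == 0 ? cb.x : (axis == 1 ? cb.y : cb.z);
                       return va < vb;
                     });
    const int l = build(start, mid - start);
    const int r = build(mid, start + count - mid);
    nodes[self].left = l; nodes[self].right = r;
    nodes[self].start = -1; nodes[self].count = 0;
    return self;
  }

  void init(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
    const int nv = Vm.nrow(), nf = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = Vec(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    F0.resize(nf); F1.resize(nf); F2.resize(nf);
    centroid.resize(nf);
    order.resize(nf);
    for (int t = 0; t < nf; ++t) {
      F0[t] = Fm(t, 0) - 1; F1[t] = Fm(t, 1) - 1; F2[t] = Fm(t, 2) - 1;
      centroid[t] = (V[F0[t]] + V[F1[t]] + V[F2[t]]) * (1.0 / 3.0);
      order[t] = t;
    }
    nodes.reserve(2 * nf / 8 + 8);
    build(0, nf);
  }

  static double box_dist2(const Node &nd, const Vec &p) {
    double d2 = 0;
    const double pc[3] = {p.x, p.y, p.z};
    for (int a = 0; a < 3; ++a) {
      double d = 0;
      if (pc[a] < nd.lo[a]) d = nd.lo[a] - pc[a];
      else if (pc[a] > nd.hi[a]) d = pc[a] - nd.hi[a];
      d2 += d * d;
    }
    return d2;
  }

  void query(const Vec &p, double &best2, Vec &bestp, int &bestt,
             double bestbary[3]) const {
    // explicit stack of node indices, nearest-box first
    int stack[128];
    int sp = 0;
    stack[sp++] = 0;
    while (sp > 0) {
      const int ni = stack[--sp];
      const Node &nd = nodes[ni];
      if (box_dist2(nd, p) >= best2) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          const int t = order[i];
          double bary[3];
          const Vec q = closest_point_triangle(p, V[F0[t]], V[F1[t]], V[F2[t]], bary);
          const Vec d = p - q;
          const double d2 = dot(d, d);
          if (d2 < best2) {
            best2 = d2; bestp = q; bestt = t;
            bestbary[0] = bary[0]; bestbary[1] = bary[1]; bestbary[2] = bary[2];
          }
        }
      } else {
        const double dl = box_dist2(nodes[nd.left], p);
        const double dr = box_dist2(nodes[nd.right], p);
        // push farther first so nearer is processed first
        if (dl < dr) { stack[sp++] = nd.right; stack[sp++] = nd.left; }
        else { stack[sp++] = nd.left; stack[sp++] = nd.right; }
      }
    }
  }
};

} // namespace

// Closest point on the mesh for each query point.
// Returns distance, closest point, 1-based triangle index, barycentrics.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix queries, NumericMatrix Vm,
                         IntegerMatrix Fm) {
  BVH bvh;
  bvh.init(Vm, Fm);
  const int nq = queries.nrow();
  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector tri(nq);
  NumericMatrix bary(nq, 3);
  for (int i = 0; i < nq; ++i) {
    const Vec p(queries(i, 0), queries(i, 1), queries(i, 2));
    double best2 = R_PosInf, bb[3] = {0, 0, 0};
    Vec bp; int bt = -1;
    bvh.query(p, best2, bp, bt, bb);
    dist[i] = std::sqrt(best2);
    closest(i, 0) = bp.x; closest(i, 1) = bp.y; closest(i, 2) = bp.z;
    tri[i] = bt + 1;
    bary(i, 0) = bb[0]; bary(i, 1) = bb[1]; bary(i, 2) = bb[2];
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["triangle"] = tri, _["bary"] = bary);
}

// Signed distance of query points to a closed, outward-oriented mesh:
// magnitude from the nearest-triangle query, sign from the angle-weighted
// pseudonormal of the closest feature (face, edge or vertex); positive
// outside, negative inside.
// [[Rcpp::export]]
List cpp_signed_distance_mesh(NumericMatrix queries, NumericMatrix Vm,
                              IntegerMatrix Fm) {
  BVH bvh;
  bvh.init(Vm, Fm);
  const int nv = Vm.nrow(), nf = Fm.nrow();
  // face normals (area-weighted direction), vertex and edge pseudonormals
  std::vector<Vec> fn(nf), vn(nv);
  std::map<std::pair<int, int>, Vec> en;
  for (int t = 0; t < nf; ++t) {
    const int i0 = bvh.F0[t], i1 = bvh.F1[t], i2 = bvh.F2[t];
    const Vec &a = bvh.V[i0], &b = bvh.V[i1], &c = bvh.V[i2];
    Vec n = cross(b - a, c - a);
    const double ln = norm(n);
    if (ln > 0) n = n * (1.0 / ln);
    fn[t] = n;
    // vertex angles
    const int idx[3] = {i0, i1, i2};
    const Vec pts[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      const Vec e1 = pts[(k + 1) % 3] - pts[k];
      const Vec e2 = pts[(k + 2) % 3] - pts[k];
      const double cosang = dot(e1, e2) / std::max(norm(e1) * norm(e2), 1e-300);
      const double ang = std::acos(std::max(-1.0, std::min(1.0, cosang)));
      vn[idx[k]] = vn[idx[k]] + n * ang;
    }
    for (int k = 0; k < 3; ++k) {
      int ea = idx[k], eb = idx[(k + 1) % 3];
      if (ea > eb) std::swap(ea, eb);
      auto key = std::make_pair(ea, eb);
      en[key] = en[key] + n;
    }
  }
  const int nq = queries.nrow();
  NumericVector sdist(nq);
  IntegerVector tri(nq);
  const double tol = 1e-9;
  for (int i = 0; i < nq; ++i) {
    const Vec p(queries(i, 0), queries(i, 1), queries(i, 2));
    double best2 = R_PosInf, bb[3];
    Vec bp; int bt = -1;
    bvh.query(p, best2, bp, bt, bb);
    const int i0 = bvh.F0[bt], i1 = bvh.F1[bt], i2 = bvh.F2[bt];
    // pick pseudonormal by closest-feature barycentric region
    Vec n;
    int nzero = (bb[0] > tol) + (bb[1] > tol) + (bb[2] > tol);
    if (nzero == 3) n = fn[bt];
    else if (nzero == 1) {
      n = bb[0] > tol ? vn[i0] : (bb[1] > tol ? vn[i1] : vn[i2]);
    } else {
      int ea, eb;
      if (bb[0] <= tol) { ea = i1; eb = i2; }
      else if (bb[1] <= tol) { ea = i0; eb = i2; }
      else { ea = i0; eb = i1; }
      if (ea > eb) std::swap(ea, eb);
      n = en[std::make_pair(ea, eb)];
    }
    const double s = dot(p - bp, n);
    const double d = std::sqrt(best2);
    sdist[i] = s >= 0 ? d : -d;
    tri[i] = bt + 1;
  }
  return List::create(_["signed"] = sdist, _["triangle"] = tri);
}

// Angle-weighted vertex normals of an oriented mesh (unit length).
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix Vm, IntegerMatrix Fm) {
  const int nv = Vm.nrow(), nf = Fm.nrow();
  std::vector<Vec> V(nv), vn(nv);
  for (int i = 0; i < nv; ++i) V[i] = Vec(Vm(i, 0), Vm(i, 1), Vm(i, 2));
  for (int t = 0; t < nf; ++t) {
    const int idx[3] = {Fm(t, 0) - 1, Fm(t, 1) - 1, Fm(t, 2) - 1};
    const Vec a = V[idx[0]], b = V[idx[1]], c = V[idx[2]];
    Vec n = cross(b - a, c - a);
    const double ln = norm(n);
    if (ln > 0) n = n * (1.0 / ln);
    const Vec pts[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      const Vec e1 = pts[(k + 1) % 3] - pts[k];
      const Vec e2 = pts[(k + 2) % 3] - pts[k];
      const double cosang = dot(e1, e2) / std::max(norm(e1) * norm(e2), 1e-300);
      const double ang = std::acos(std::max(-1.0, std::min(1.0, cosang)));
      vn[idx[k]] = vn[idx[k]] + n * ang;
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) {
    const double ln = norm(vn[i]);
    const double s = ln > 0 ? 1.0 / ln : 0.0;
    out(i, 0) = vn[i].x * s; out(i, 1) = vn[i].y * s; out(i, 2) = vn[i].z * s;
  }
  return out;
}
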