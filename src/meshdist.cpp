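#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Signed perpendicular distances from query vertices (with unit normals) to a
// target triangle mesh: for each vertex, shoot the bidirectional line
// v + s * n through every target triangle (Moller-Trumbore) and keep the
// intersection with the smallest |s| within the cap. Sign is the ray
// parameter itself: positive when the target surface lies on the outward
// (+n) side. When no intersection falls inside the cap the nearest
// point-to-triangle distance is used instead, signed by the parity of
// forward crossings (odd = vertex inside the target surface = positive),
// and the vertex is flagged as a fallback.

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// squared distance from point p to triangle (a,b,c) (Ericson, Real-Time
// Collision Detection, closest-point-on-triangle)
double pointTriDistSq(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { Vec3 d = ap; return dot(d, d); }
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { Vec3 d = bp; return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    Vec3 q = {a.x + v * ab.x, a.y + v * ab.y, a.z + v * ab.z};
    Vec3 d = sub(p, q); return dot(d, d);
  }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { Vec3 d = cp; return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    Vec3 q = {a.x + w * ac.x, a.y + w * ac.y, a.z + w * ac.z};
    Vec3 d = sub(p, q); return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 q = {b.x + w * (c.x - b.x), b.y + w * (c.y - b.y), b.z + w * (c.z - b.z)};
    Vec3 d = sub(p, q); return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  Vec3 q = {a.x + v * ab.x + w * ac.x, a.y + v * ab.y + w * ac.y,
            a.z + v * ab.z + w * ac.z};
  Vec3 d = sub(p, q); return dot(d, d);
}

} // namespace

// [[Rcpp::export(name = ".cpp_signed_normal_dist")]]
List cpp_signed_normal_dist(NumericMatrix verts, NumericMatrix normals,
                            NumericMatrix tv, IntegerMatrix tf, double cap) {
  const int nv = verts.nrow();
  const int nt = tf.nrow();
  NumericVector dist(nv);
  LogicalVector fallback(nv);
  const double EPS = 1e-12;

  for (int i = 0; i < nv; ++i) {
    Vec3 o = {verts(i, 0), verts(i, 1), verts(i, 2)};
    Vec3 dir = {normals(i, 0), normals(i, 1), normals(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    double bestSq = std::numeric_limits<double>::infinity();
    int fwd = 0; // forward (s > 0) crossings for parity
    bool hit = false;

    for (int t = 0; t < nt; ++t) {
      Vec3 a = {tv(tf(t, 0) - 1, 0), tv(tf(t, 0) - 1, 1), tv(tf(t, 0) - 1, 2)};
      Vec3 b = {tv(tf(t, 1) - 1, 0), tv(tf(t, 1) - 1, 1), tv(tf(t, 1) - 1, 2)};
      Vec3 c = {tv(tf(t, 2) - 1, 0), tv(tf(t, 2) - 1, 1), tv(tf(t, 2) - 1, 2)};

      // Moller-Trumbore, both directions
      Vec3 e1 = sub(b, a), e2 = sub(c, a);
      Vec3 p = cross(dir, e2);
      double det = dot(e1, p);
      if (std::fabs(det) > EPS) {
        double inv = 1.0 / det;
        Vec3 tvec = sub(o, a);
        double u = dot(tvec, p) * inv;
        if (u >= -1e-9 && u <= 1 + 1e-9) {
          Vec3 q = cross(tvec, e1);
          double v = dot(dir, q) * inv;
          if (v >= -1e-9 && u + v <= 1 + 1e-9) {
            double s = dot(e2, q) * inv;
            if (s > EPS) ++fwd;
            if (std::fabs(s) < std::fabs(best)) best = s;
            if (std::fabs(s) <= cap) hit = true;
          }
        }
      }
      double dsq = pointTriDistSq(o, a, b, c);
      if (dsq < bestSq) bestSq = dsq;
    }

    if (hit) {
      dist[i] = best;
      fallback[i] = false;
    } else {
      double d = std::sqrt(bestSq);
      dist[i] = (fwd % 2 == 1) ? d : -d;
      fallback[i] = true;
    }
  }
  return List::create(_["distance"] = dist, _["fallback"] = fallback);
}
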