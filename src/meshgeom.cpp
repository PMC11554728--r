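#include "common.h"
#include "contact.h"
#include <map>
using namespace Rcpp;

// Closest point on a triangle to q (Ericson, Real-Time Collision Detection).
// feature: 0 face; 1 edge ab, 2 edge bc, 3 edge ca; 4/5/6 vertex a/b/c.
V3 closest_point_triangle(const V3& q, const V3& a, const V3& b, const V3& c, int* feature) {
  V3 ab = b - a, ac = c - a, aq = q - a;
  double d1 = dot(ab, aq), d2 = dot(ac, aq);
  if (d1 <= 0.0 && d2 <= 0.0) { *feature = 4; return a; }
  V3 bq = q - b;
  double d3 = dot(ab, bq), d4 = dot(ac, bq);
  if (d3 >= 0.0 && d4 <= d3) { *feature = 5; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    *feature = 1; return a + v * ab;
  }
  V3 cq = q - c;
  double d5 = dot(ab, cq), d6 = dot(ac, cq);
  if (d6 >= 0.0 && d5 <= d6) { *feature = 6; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    *feature = 3; return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    *feature = 2; return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  *feature = 0;
  return a + v * ab + w * ac;
}

// Signed distance to a closed, outward-oriented triangle mesh: exact
// point-to-mesh distance (octree-accelerated) with the sign taken from
// angle-weighted pseudonormals at the closest feature.  Negative inside.
struct SdfMesh {
  WallMesh wm;
  std::vector<V3> vnormal;            // angle-weighted vertex pseudonormals
  std::map<std::pair<int, int>, V3> enormal;  // edge pseudonormals
  double typ;                          // typical triangle size

  void init(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    wm.init(Vm, Fm);
    int nv = Vm.nrow();
    vnormal.assign(nv, V3());
    typ = 0.0;
    for (int k = 0; k < wm.nf; ++k) {
      int i0 = wm.f0[k], i1 = wm.f1[k], i2 = wm.f2[k];
      const V3 &a = wm.vert[i0], &b = wm.vert[i1], &c = wm.vert[i2];
      const V3& n = wm.fnormal[k];
      typ = std::max(typ, wm.rst[k]);
      // interior angles
      auto ang = [](const V3& u, const V3& v) {
        double d = dot(normalize(u), normalize(v));
        return std::acos(std::max(-1.0, std::min(1.0, d)));
      };
      vnormal[i0] += ang(b - a, c - a) * n;
      vnormal[i1] += ang(a - b, c - b) * n;
      vnormal[i2] += ang(a - c, b - c) * n;
      auto ekey = [](int i, int j) { return std::make_pair(std::min(i, j), std::max(i, j)); };
      enormal[ekey(i0, i1)] += n;
      enormal[ekey(i1, i2)] += n;
      enormal[ekey(i2, i0)] += n;
    }
  }

  double sdist(const V3& p, std::vector<int>& hits) const {
    double r = 2.0 * typ;
    double best = R_PosInf;
    int bestk = -1, bestfeat = 0;
    V3 bestcp;
    for (int iter = 0; iter < 64; ++iter) {
      wm.tree.query(p, r, hits);
      if (!hits.empty()) break;
      r *= 2.0;
    }
    // two passes: min over current hits, then a guaranteed re-query
    for (int pass = 0; pass < 2; ++pass) {
      for (size_t h = 0; h < hits.size(); ++h) {
        int k = hits[h];
        int feat;
        V3 cp = closest_point_triangle(p, wm.vert[wm.f0[k]], wm.vert[wm.f1[k]], wm.vert[wm.f2[k]], &feat);
        double d = norm(p - cp);
        if (d < best) { best = d; bestk = k; bestfeat = feat; bestcp = cp; }
      }
      if (pass == 0) {
        if (bestk < 0) return R_PosInf;
        if (best >= r) { r = best * 1.0000001; wm.tree.query(p, r, hits); }
        else break;  // all triangles within reach already examined
      }
    }
    // pseudonormal sign
    V3 pn;
    int k = bestk;
    auto ekey = [](int i, int j) { return std::make_pair(std::min(i, j), std::max(i, j)); };
    switch (bestfeat) {
      case 0: pn = wm.fnormal[k]; break;
      case 1: pn = enormal.find(ekey(wm.f0[k], wm.f1[k]))->second; break;
      case 2: pn = enormal.find(ekey(wm.f1[k], wm.f2[k]))->second; break;
      case 3: pn = enormal.find(ekey(wm.f2[k], wm.f0[k]))->second; break;
      case 4: pn = vnormal[wm.f0[k]]; break;
      case 5: pn = vnormal[wm.f1[k]]; break;
      default: pn = vnormal[wm.f2[k]]; break;
    }
    double s = dot(p - bestcp, pn) >= 0.0 ? 1.0 : -1.0;
    return s * best;
  }
};

// [[Rcpp::export]]
NumericVector cpp_mesh_sdf(NumericMatrix Vm, IntegerMatrix Fm, NumericMatrix P) {
  SdfMesh sm;
  sm.init(Vm, Fm);
  int n = P.nrow();
  NumericVector out(n);
  std::vector<int> hits;
  for (int i = 0; i < n; ++i)
    out[i] = sm.sdist(V3(P(i, 0), P(i, 1), P(i, 2)), hits);
  return out;
}

// Binary voxelization of the capsule union swept by a circle of radius r
// along the polyline: voxel value 1 iff its center lies within r of the
// centerline.  Grid: NV^3 cubes of size a/NV anchored at origin; linear
// index i + NV*(j + NV*k) (x fastest), matching R array order.
// [[Rcpp::export]]
NumericVector cpp_voxelize_polyline(NumericMatrix XL, double r, NumericVector origin,
                                    double a, int NV) {
  double h = a / NV;
  NumericVector out((R_xlen_t)NV * NV * NV);
  int n = XL.nrow();
  for (int seg = 0; seg + 1 < n; ++seg) {
    V3 p(XL(seg, 0) - origin[0], XL(seg, 1) - origin[1], XL(seg, 2) - origin[2]);
    V3 q(XL(seg + 1, 0) - origin[0], XL(seg + 1, 1) - origin[1], XL(seg + 1, 2) - origin[2]);
    double lo[3] = { std::min(p.x, q.x) - r, std::min(p.y, q.y) - r, std::min(p.z, q.z) - r };
    double hi[3] = { std::max(p.x, q.x) + r, std::max(p.y, q.y) + r, std::max(p.z, q.z) + r };
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = std::max(0, (int)std::floor(lo[d] / h - 0.5));
      i1[d] = std::min(NV - 1, (int)std::ceil(hi[d] / h - 0.5));
    }
    V3 dseg = q - p;
    double L2 = dot(dseg, dseg);
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i) {
          V3 c(h * (i + 0.5), h * (j + 0.5), h * (k + 0.5));
          V3 w = c - p;
          double t = L2 > 0 ? std::max(0.0, std::min(1.0, dot(w, dseg) / L2)) : 0.0;
          V3 dv = w - t * dseg;
          if (dot(dv, dv) <= r * r)
            out[i + (R_xlen_t)NV * (j + (R_xlen_t)NV * k)] = 1.0;
        }
  }
  return out;
}
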