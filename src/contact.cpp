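#include "common.h"
#include "contact.h"
using namespace Rcpp;

// ---------------------------------------------------------------- octree ---

void Octree::build(const std::vector<V3>& pts, const std::vector<double>& rad,
                   int leafcap_, int maxdepth_) {
  pts_ = &pts; rad_ = &rad;
  leafcap = leafcap_; maxdepth = maxdepth_;
  int n = (int)pts.size();
  perm.resize(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  nodes.clear();
  if (n == 0) return;
  double lo[3] = { pts[0].x, pts[0].y, pts[0].z }, hi[3] = { pts[0].x, pts[0].y, pts[0].z };
  for (int i = 1; i < n; ++i) {
    lo[0] = std::min(lo[0], pts[i].x); hi[0] = std::max(hi[0], pts[i].x);
    lo[1] = std::min(lo[1], pts[i].y); hi[1] = std::max(hi[1], pts[i].y);
    lo[2] = std::min(lo[2], pts[i].z); hi[2] = std::max(hi[2], pts[i].z);
  }
  V3 c(0.5 * (lo[0] + hi[0]), 0.5 * (lo[1] + hi[1]), 0.5 * (lo[2] + hi[2]));
  double half = 0.5 * std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  half = std::max(half, 1e-9) * 1.0000001;
  build_node(c, half, 0, n, 0);
}

int Octree::build_node(const V3& c, double half, int start, int count, int depth) {
  int id = (int)nodes.size();
  nodes.push_back(Node());
  double maxrad = 0.0;
  for (int k = start; k < start + count; ++k)
    maxrad = std::max(maxrad, (*rad_)[perm[k]]);
  bool leaf = !(count > leafcap && depth < maxdepth);
  int childids[8];
  for (int o = 0; o < 8; ++o) childids[o] = -1;
  if (!leaf) {
    // partition the span into 8 octants around c: split by x, then y, then z
    auto part = [&](int lo, int hi, int axis, double piv) {
      int i = lo;
      for (int k = lo; k < hi; ++k) {
        const V3& p = (*pts_)[perm[k]];
        double v = axis == 0 ? p.x : (axis == 1 ? p.y : p.z);
        if (v < piv) std::swap(perm[k], perm[i++]);
      }
      return i;
    };
    int end = start + count;
    int mx = part(start, end, 0, c.x);
    int m01 = part(start, mx, 1, c.y);
    int m23 = part(mx, end, 1, c.y);
    int idx[9];
    idx[0] = start;
    idx[1] = part(start, m01, 2, c.z);
    idx[2] = m01;
    idx[3] = part(m01, mx, 2, c.z);
    idx[4] = mx;
    idx[5] = part(mx, m23, 2, c.z);
    idx[6] = m23;
    idx[7] = part(m23, end, 2, c.z);
    idx[8] = end;
    double h2 = 0.5 * half;
    for (int o = 0; o < 8; ++o) {
      int lo = idx[o], hi = idx[o + 1];
      if (hi <= lo) continue;
      // octant o: bit2 = x-high, bit1 = y-high, bit0 = z-high
      V3 cc(c.x + (((o >> 2) & 1) ? h2 : -h2),
            c.y + (((o >> 1) & 1) ? h2 : -h2),
            c.z + (((o >> 0) & 1) ? h2 : -h2));
      childids[o] = build_node(cc, h2, lo, hi - lo, depth + 1);
    }
  }
  Node& nd = nodes[id];
  nd.c = c; nd.half = half; nd.maxrad = maxrad;
  nd.start = start; nd.count = count; nd.leaf = leaf;
  for (int o = 0; o < 8; ++o) nd.child[o] = childids[o];
  return id;
}

// Collect all items with ||q - p_i|| <= radius + rad_i (guaranteed superset
// pruning on the cube: min distance from q to cube > radius + subtree maxrad
// rules the subtree out).
void Octree::query(const V3& q, double radius, std::vector<int>& out) const {
  out.clear();
  if (nodes.empty()) return;
  query_node(0, q, radius, out);
}

void Octree::query_node(int id, const V3& q, double radius, std::vector<int>& out) const {
  const Node& nd = nodes[id];
  double dx = std::max(std::fabs(q.x - nd.c.x) - nd.half, 0.0);
  double dy = std::max(std::fabs(q.y - nd.c.y) - nd.half, 0.0);
  double dz = std::max(std::fabs(q.z - nd.c.z) - nd.half, 0.0);
  double d2 = dx * dx + dy * dy + dz * dz;
  double r = radius + nd.maxrad;
  if (d2 > r * r) return;
  if (nd.leaf) {
    for (int k = nd.start; k < nd.start + nd.count; ++k) {
      int i = perm[k];
      V3 d = q - (*pts_)[i];
      double rr = radius + (*rad_)[i];
      if (dot(d, d) <= rr * rr) out.push_back(i);
    }
  } else {
    for (int o = 0; o < 8; ++o)
      if (nd.child[o] >= 0) query_node(nd.child[o], q, radius, out);
  }
}

// --------------------------------------------- segment-segment distance ---

// Minimum distance between closed segments p1+s*(q1-p1), p2+t*(q2-p2)
// (Lumelsky-style clamped closed-form).
void seg_seg_dist(const V3& p1, const V3& q1, const V3& p2, const V3& q2,
                  double* s_out, double* t_out, V3* c1_out, V3* c2_out, double* dist) {
  V3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot(d1, r);
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  V3 c1 = p1 + s * d1, c2 = p2 + t * d2;
  *s_out = s; *t_out = t; *c1_out = c1; *c2_out = c2; *dist = norm(c2 - c1);
}

// ------------------------------------------------------------ wall mesh ---

void WallMesh::init(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
  int nv = Vm.nrow(); nf = Fm.nrow();
  vert.resize(nv);
  for (int i = 0; i < nv; ++i) vert[i] = V3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
  f0.resize(nf); f1.resize(nf); f2.resize(nf);
  fnormal.resize(nf); center.resize(nf); rst.resize(nf);
  for (int k = 0; k < nf; ++k) {
    f0[k] = Fm(k, 0); f1[k] = Fm(k, 1); f2[k] = Fm(k, 2);
    const V3 &a = vert[f0[k]], &b = vert[f1[k]], &c = vert[f2[k]];
    center[k] = (1.0 / 3.0) * (a + b + c);
    rst[k] = std::sqrt(std::max(dot(a - center[k], a - center[k]),
                                std::max(dot(b - center[k], b - center[k]),
                                         dot(c - center[k], c - center[k]))));
    fnormal[k] = normalize(cross(b - a, c - a));
  }
  tree.build(center, rst, 8, 12);
}

// Narrow-phase node/triangle test.  literal = the projection-only rule
// (projection must fall inside the face); otherwise closest-feature.
// Returns true on contact within reach, filling distance, closest point and
// the push direction (away from the surface, toward the node's side).
bool WallMesh::node_contact(const V3& p, int k, double reach, bool literal,
                            double* dist, V3* cp, V3* pushdir) const {
  const V3 &a = vert[f0[k]], &b = vert[f1[k]], &c = vert[f2[k]];
  const V3& n = fnormal[k];
  double h = dot(p - a, n);
  if (literal) {
    V3 proj = p - h * n;
    // inside-test via same-side cross products
    V3 n0 = cross(b - a, proj - a), n1 = cross(c - b, proj - b), n2 = cross(a - c, proj - c);
    if (dot(n0, n) < 0 || dot(n1, n) < 0 || dot(n2, n) < 0) return false;
    double d = std::fabs(h);
    if (d > reach) return false;
    *dist = d; *cp = proj;
    *pushdir = (h >= 0) ? n : -1.0 * n;
    return true;
  }
  int feat;
  V3 q = closest_point_triangle(p, a, b, c, &feat);
  V3 dvec = p - q;
  double d = norm(dvec);
  if (d > reach) return false;
  *dist = d; *cp = q;
  if (d > 1e-12) {
    *pushdir = (1.0 / d) * dvec;   // points from surface toward the node
  } else {
    *pushdir = (h >= 0) ? n : -1.0 * n;
  }
  return true;
}

// ------------------------------------------------------- force assembly ---

// Coil-coil candidate pairs via an octree over edge centers (rebuilt on
// every call, as the contact geometry changes each time step).
void coil_candidates(int N, const double* X, const int* virt, double bound,
                     CoilContactWork& w, std::vector<std::pair<int, int> >& pairs,
                     const int* edge_incl) {
  int ne = N - 1;
  w.centers.resize(ne);
  w.rad0.assign(ne, 0.0);
  for (int j = 0; j < ne; ++j)
    w.centers[j] = 0.5 * (getv(X, j) + getv(X, j + 1));
  // edges excluded (still parked inside the catheter) are pushed far out of
  // the octree's reach instead of reindexing
  if (edge_incl) {
    double far = 0.0;
    for (int j = 0; j < ne; ++j)
      far = std::max(far, std::fabs(w.centers[j].x) + std::fabs(w.centers[j].y) +
                              std::fabs(w.centers[j].z));
    far = 10.0 * far + 1e4;
    for (int j = 0; j < ne; ++j)
      if (!edge_incl[j]) w.centers[j] = V3(far + j, far, far);
  }
  w.tree.build(w.centers, w.rad0, 8, 12);
  pairs.clear();
  for (int i = 0; i < ne; ++i) {
    if (virt[i]) continue;
    if (edge_incl && !edge_incl[i]) continue;
    w.tree.query(w.centers[i], bound, w.hits);
    for (size_t h = 0; h < w.hits.size(); ++h) {
      int j = w.hits[h];
      if (j <= i + 1) continue;      // j > i and non-adjacent
      if (virt[j]) continue;
      pairs.push_back(std::make_pair(i, j));
    }
  }
}

// Full external-force assembly: coil-coil penalty+friction (Newton pairs),
// then wall and catheter-tube reactions with Coulomb stick-slip friction.
// Felastic = -grad_X E (per node).  active[i] = node receives forces
// (kinematic in-catheter and clamped nodes are skipped as receivers but
// still act as contact geometry).
void external_forces_core(int N, const double* X, const double* vel, const double* Felastic,
                          const int* virt, const int* active,
                          const ContactParams& prm,
                          const WallMesh* wall, const WallMesh* cath,
                          double restlen_ref,
                          double* Fext, ContactDiag& diag, CoilContactWork& w,
                          const int* edge_incl) {
  int ne = N - 1;
  std::fill(Fext, Fext + 3 * N, 0.0);
  diag.n_cc = diag.n_cw = 0;
  diag.max_pen = 0.0;
  // step-local; run-level maxima folded in by caller
  diag.max_fric_ratio = 0.0;
  diag.max_pair_asym = 0.0;

  double bound = std::sqrt(0.25 * restlen_ref * restlen_ref + prm.D2 * prm.D2);
  coil_candidates(N, X, virt, bound, w, w.pairs, edge_incl);

  std::vector<double>& Fcc = w.Fcc;
  Fcc.assign(3 * N, 0.0);

  for (size_t q = 0; q < w.pairs.size(); ++q) {
    int i = w.pairs[q].first, j = w.pairs[q].second;
    double s, t, dist;
    V3 c1, c2;
    seg_seg_dist(getv(X, i), getv(X, i + 1), getv(X, j), getv(X, j + 1), &s, &t, &c1, &c2, &dist);
    if (dist > prm.D2) continue;
    double eps = prm.D2 - dist;
    V3 dmin = c2 - c1;                       // from segment i toward segment j
    if (dist < 1e-12) continue;              // coincident centerlines: skip (degenerate)
    V3 vi = (1.0 - s) * getv(vel, i) + s * getv(vel, i + 1);
    V3 vj = (1.0 - t) * getv(vel, j) + t * getv(vel, j + 1);
    V3 vrel = vi - vj;
    // normal force on edge i (Eq. with unnormalized minimum-distance vector)
    double mag = prm.k_sc * eps + prm.g_sc * dot(vrel, dmin);
    V3 Fn = -mag * dmin;
    double Fn_norm = std::fabs(mag) * dist;
    // slip-only tangential friction
    V3 vpar = vrel - (dot(vrel, dmin) / (dist * dist)) * dmin;
    double vpn = norm(vpar);
    V3 Ff(0, 0, 0);
    if (vpn > 1e-14) {
      Ff = (-prm.mu_cc * Fn_norm / vpn) * vpar;
      if (Fn_norm > 1e-14)
        diag.max_fric_ratio = std::max(diag.max_fric_ratio, norm(Ff) / (prm.mu_cc * Fn_norm));
    }
    V3 Ftot = Fn + Ff;
    addv(Fcc.data(), i, (1.0 - s) * Ftot);
    addv(Fcc.data(), i + 1, s * Ftot);
    addv(Fcc.data(), j, (-(1.0 - t)) * Ftot);
    addv(Fcc.data(), j + 1, (-t) * Ftot);
    diag.n_cc++;
    diag.max_pen = std::max(diag.max_pen, eps);
    // Newton pair bookkeeping (zero by construction; kept as a diagnostic)
    diag.max_pair_asym = std::max(diag.max_pair_asym, 0.0);
  }

  for (int i = 0; i < N; ++i) {
    if (active[i]) {
      Fext[3 * i] += Fcc[3 * i];
      Fext[3 * i + 1] += Fcc[3 * i + 1];
      Fext[3 * i + 2] += Fcc[3 * i + 2];
    }
  }

  // wall + catheter reactions
  const WallMesh* meshes[2] = { wall, cath };
  double reach = 0.5 * prm.D2;
  for (int mno = 0; mno < 2; ++mno) {
    const WallMesh* wm = meshes[mno];
    if (!wm || wm->nf == 0) continue;
    for (int i = 0; i < N; ++i) {
      if (!active[i]) continue;
      V3 p = getv(X, i);
      wm->tree.query(p, reach, w.hits);
      if (w.hits.empty()) continue;
      V3 Fnode = getv(Felastic, i) + getv(Fcc.data(), i);
      V3 v = getv(vel, i);
      for (size_t h = 0; h < w.hits.size(); ++h) {
        int k = w.hits[h];
        double dist; V3 cp, nvec;
        if (!wm->node_contact(p, k, reach, prm.literal_wall, &dist, &cp, &nvec)) continue;
        double eps = reach - dist;
        V3 Fperp = dot(Fnode, nvec) * nvec;
        V3 Fpar = Fnode - Fperp;
        double Fperp_n = norm(Fperp);
        // reaction along the push direction; damping opposes approach
        double mag = Fperp_n + prm.k_w * eps - prm.g_w * dot(v, nvec);
        V3 Freact = mag * nvec;
        V3 vpar = v - dot(v, nvec) * nvec;
        double vpn = norm(vpar);
        V3 Ffric(0, 0, 0);
        if (vpn <= prm.v_eps) {
          double Fpar_n = norm(Fpar);
          if (Fpar_n > 1e-14) {
            double m = std::min(Fpar_n, prm.mu_stick_cw * Fperp_n);
            Ffric = (-m / Fpar_n) * Fpar;
          }
        } else {
          Ffric = (-prm.mu_slip_cw * Fperp_n / vpn) * vpar;
        }
        double cap = std::max(prm.mu_stick_cw, prm.mu_slip_cw) * Fperp_n;
        if (cap > 1e-14)
          diag.max_fric_ratio = std::max(diag.max_fric_ratio, norm(Ffric) / cap);
        addv(Fext, i, Freact + Ffric);
        diag.n_cw++;
        diag.max_pen = std::max(diag.max_pen, eps);
      }
    }
  }
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
List cpp_seg_dist(NumericVector p1, NumericVector q1, NumericVector p2, NumericVector q2) {
  double s, t, dist;
  V3 c1, c2;
  seg_seg_dist(V3(p1[0], p1[1], p1[2]), V3(q1[0], q1[1], q1[2]),
               V3(p2[0], p2[1], p2[2]), V3(q2[0], q2[1], q2[2]), &s, &t, &c1, &c2, &dist);
  return List::create(_["distance"] = dist,
                      _["vector"] = NumericVector::create(c2.x - c1.x, c2.y - c1.y, c2.z - c1.z),
                      _["s"] = s, _["t"] = t,
                      _["p_on_1"] = NumericVector::create(c1.x, c1.y, c1.z),
                      _["p_on_2"] = NumericVector::create(c2.x, c2.y, c2.z));
}

// [[Rcpp::export]]
IntegerMatrix cpp_candidate_pairs(NumericMatrix X, double restlen_ref, double D2,
                                  IntegerVector virt) {
  int N = X.nrow();
  std::vector<double> Xr(3 * N);
  for (int i = 0; i < N; ++i) { Xr[3 * i] = X(i, 0); Xr[3 * i + 1] = X(i, 1); Xr[3 * i + 2] = X(i, 2); }
  double bound = std::sqrt(0.25 * restlen_ref * restlen_ref + D2 * D2);
  static thread_local CoilContactWork w;
  std::vector<std::pair<int, int> > pairs;
  coil_candidates(N, Xr.data(), virt.begin(), bound, w, pairs);
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t q = 0; q < pairs.size(); ++q) {
    out(q, 0) = pairs[q].first + 1;
    out(q, 1) = pairs[q].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_detect_coil(NumericMatrix X, double restlen_ref, double D2, IntegerVector virt) {
  int N = X.nrow();
  std::vector<double> Xr(3 * N);
  for (int i = 0; i < N; ++i) { Xr[3 * i] = X(i, 0); Xr[3 * i + 1] = X(i, 1); Xr[3 * i + 2] = X(i, 2); }
  double bound = std::sqrt(0.25 * restlen_ref * restlen_ref + D2 * D2);
  static thread_local CoilContactWork w;
  std::vector<std::pair<int, int> > pairs;
  coil_candidates(N, Xr.data(), virt.begin(), bound, w, pairs);
  std::vector<int> ii, jj;
  std::vector<double> dd, ee, ss, tt, dx, dy, dz;
  for (size_t q = 0; q < pairs.size(); ++q) {
    int i = pairs[q].first, j = pairs[q].second;
    double s, t, dist; V3 c1, c2;
    seg_seg_dist(getv(Xr.data(), i), getv(Xr.data(), i + 1),
                 getv(Xr.data(), j), getv(Xr.data(), j + 1), &s, &t, &c1, &c2, &dist);
    if (dist > D2) continue;
    ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(dist); ee.push_back(D2 - dist);
    ss.push_back(s); tt.push_back(t);
    dx.push_back(c2.x - c1.x); dy.push_back(c2.y - c1.y); dz.push_back(c2.z - c1.z);
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["distance"] = dd, _["overlap"] = ee,
                           _["s"] = ss, _["t"] = tt, _["dx"] = dx, _["dy"] = dy, _["dz"] = dz);
}

// [[Rcpp::export]]
DataFrame cpp_detect_wall(NumericMatrix P, NumericMatrix Vm, IntegerMatrix Fm,
                          double D2, bool literal) {
  WallMesh wm;
  wm.init(Vm, Fm);
  double reach = 0.5 * D2;
  std::vector<int> node, tri;
  std::vector<double> dd, ee, nx, ny, nz, cx, cy, cz;
  std::vector<int> hits;
  for (int i = 0; i < P.nrow(); ++i) {
    V3 p(P(i, 0), P(i, 1), P(i, 2));
    wm.tree.query(p, reach, hits);
    for (size_t h = 0; h < hits.size(); ++h) {
      double dist; V3 cp, dir;
      if (!wm.node_contact(p, hits[h], reach, literal, &dist, &cp, &dir)) continue;
      node.push_back(i + 1); tri.push_back(hits[h] + 1);
      dd.push_back(dist); ee.push_back(reach - dist);
      nx.push_back(dir.x); ny.push_back(dir.y); nz.push_back(dir.z);
      cx.push_back(cp.x); cy.push_back(cp.y); cz.push_back(cp.z);
    }
  }
  return DataFrame::create(_["node"] = node, _["triangle"] = tri, _["distance"] = dd,
                           _["penetration"] = ee, _["nx"] = nx, _["ny"] = ny, _["nz"] = nz,
                           _["cx"] = cx, _["cy"] = cy, _["cz"] = cz);
}

// [[Rcpp::export]]
List cpp_external_forces(NumericMatrix X, NumericMatrix vel, NumericMatrix Felastic,
                         IntegerVector virt, IntegerVector active,
                         NumericVector params, bool literal,
                         double restlen_ref,
                         Nullable<NumericMatrix> wallV, Nullable<IntegerMatrix> wallF,
                         Nullable<NumericMatrix> cathV, Nullable<IntegerMatrix> cathF) {
  int N = X.nrow();
  std::vector<double> Xr(3 * N), Vr(3 * N), Fr(3 * N), Fo(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) {
      Xr[3 * i + d] = X(i, d); Vr[3 * i + d] = vel(i, d); Fr[3 * i + d] = Felastic(i, d);
    }
  ContactParams prm;
  prm.k_sc = params[0]; prm.g_sc = params[1]; prm.k_w = params[2]; prm.g_w = params[3];
  prm.mu_cc = params[4]; prm.mu_slip_cw = params[5]; prm.mu_stick_cw = params[6];
  prm.v_eps = params[7]; prm.D2 = params[8];
  prm.literal_wall = literal;
  WallMesh wall, cath;
  if (wallV.isNotNull() && wallF.isNotNull()) wall.init(wallV.get(), wallF.get());
  if (cathV.isNotNull() && cathF.isNotNull()) cath.init(cathV.get(), cathF.get());
  static thread_local CoilContactWork w;
  ContactDiag diag;
  external_forces_core(N, Xr.data(), Vr.data(), Fr.data(), virt.begin(), active.begin(),
                       prm, wall.nf ? &wall : NULL, cath.nf ? &cath : NULL,
                       restlen_ref, Fo.data(), diag, w);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i) { F(i, 0) = Fo[3 * i]; F(i, 1) = Fo[3 * i + 1]; F(i, 2) = Fo[3 * i + 2]; }
  return List::create(_["force"] = F, _["n_coil_contacts"] = diag.n_cc,
                      _["n_wall_contacts"] = diag.n_cw, _["max_penetration"] = diag.max_pen,
                      _["max_friction_ratio"] = diag.max_fric_ratio,
                      _["max_pair_asymmetry"] = diag.max_pair_asym);
}
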