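#include "common.h"
using namespace Rcpp;

// Discrete elastic rod energy on a polyline with per-edge adapted frames.
//
// State: vertices X (N x 3), edge angles phi (N-1) giving material directors
//   D1 = cos(phi) U + sin(phi) V,  D2 = -sin(phi) U + cos(phi) V
// relative to the stored per-edge reference triads {U, V, t}.  When the
// stored triads are the space-propagated Bishop frame the reference twist at
// every interior node is zero and the measured twist reduces to the angle
// increment phi^j - phi^{j-1}; the energy below supports arbitrary adapted
// reference frames by measuring the reference twist explicitly, which is
// also what makes finite differencing of the energy well defined (perturbed
// configurations carry time-parallel-transported copies of the frames).
//
// Energy (per unit system mN, mm):
//   E = sum_edges  alpha_j/2 (|e^j|/|ebar^j| - 1)^2 |ebar^j|
//     + sum_nodes  b_i /(2 lbar_i) |kappa_i - kbar_i|^2
//     + sum_nodes  beta_i/(2 lbar_i) tau_i^2
// with integrated nodal curvatures from the curvature binormal and the
// twist tau_i = phi^i - phi^{i-1} + reftwist_i at interior node i.
// Virtual connector edges (multi-coil chains) carry no elastic terms and
// break the frame chain.

struct RodP {
  int N, ne;
  const double *elbar;     // ne rest edge lengths
  const double *lbar;      // N nodal Voronoi lengths (interior entries used)
  const double *kbar;      // N x 2 natural curvatures, row-major (k1, k2)
  const double *alpha;     // ne axial penalty stiffness (absolute, mN)
  const double *bnode;     // N bending stiffness (mN mm^2)
  const double *betanode;  // N twisting stiffness (mN mm^2)
  const int *virt;         // ne flags: 1 = virtual connector edge
};

struct RodWork {
  std::vector<V3> t, D1, D2, kb;
  std::vector<double> len, tau, Aedge, kap1, kap2;
  std::vector<char> nodeok;
  void resize(int N) {
    int ne = N - 1;
    t.resize(ne); D1.resize(ne); D2.resize(ne);
    kb.resize(N); len.resize(ne); tau.resize(N);
    Aedge.resize(ne); kap1.resize(N); kap2.resize(N);
    nodeok.resize(N);
  }
};

// Core evaluation.  gX (3N) and gPhi (ne) may be NULL for energy-only.
// comps: axial, bending, twist energies.
static double rod_energy_grad_core(const RodP& rp, const double* X, const double* phi,
                                   const double* Uf, const double* Vf,
                                   double* gX, double* gPhi, double* comps,
                                   RodWork& w, bool zero_reftwist = false) {
  const int N = rp.N, ne = rp.ne;
  w.resize(N);
  double Eax = 0.0, Ebend = 0.0, Etw = 0.0;

  for (int j = 0; j < ne; ++j) {
    V3 e = getv(X, j + 1) - getv(X, j);
    double l = norm(e);
    if (!(l > 0.0)) stop("zero-length edge %d", j);
    w.len[j] = l;
    w.t[j] = (1.0 / l) * e;
    double c = std::cos(phi[j]), s = std::sin(phi[j]);
    V3 U = getv(Uf, j), V = getv(Vf, j);
    w.D1[j] = c * U + s * V;
    w.D2[j] = -1.0 * s * U + c * V;
    if (!rp.virt[j]) {
      double str = l / rp.elbar[j] - 1.0;
      Eax += 0.5 * rp.alpha[j] * str * str * rp.elbar[j];
    }
  }

  for (int i = 1; i < N - 1; ++i) {
    bool ok = !rp.virt[i - 1] && !rp.virt[i];
    w.nodeok[i] = ok;
    if (!ok) continue;
    double cdot = dot(w.t[i - 1], w.t[i]);
    if (cdot <= -1.0 + 1e-10)
      stop("degenerate turn at node %d: antiparallel tangents", i);
    w.kb[i] = (2.0 / (1.0 + cdot)) * cross(w.t[i - 1], w.t[i]);
    double k1 = 0.5 * dot(w.D2[i - 1] + w.D2[i], w.kb[i]);
    double k2 = -0.5 * dot(w.D1[i - 1] + w.D1[i], w.kb[i]);
    w.kap1[i] = k1; w.kap2[i] = k2;
    // reference twist of the stored frames at this node (identically zero
    // for freshly propagated Bishop frames; the gradient still carries the
    // holonomy terms)
    double reftw = 0.0;
    if (!zero_reftwist) {
      V3 up = par_transport(w.t[i - 1], w.t[i], getv(Uf, i - 1));
      reftw = signed_angle(up, getv(Uf, i), w.t[i]);
    }
    double tau = wrap_angle(phi[i] - phi[i - 1] + reftw);
    w.tau[i] = tau;
    double dk1 = k1 - rp.kbar[2 * i], dk2 = k2 - rp.kbar[2 * i + 1];
    Ebend += 0.5 * rp.bnode[i] / rp.lbar[i] * (dk1 * dk1 + dk2 * dk2);
    Etw += 0.5 * rp.betanode[i] / rp.lbar[i] * tau * tau;
  }

  if (comps) { comps[0] = Eax; comps[1] = Ebend; comps[2] = Etw; }
  double E = Eax + Ebend + Etw;
  if (!gX && !gPhi) return E;

  if (gX) std::fill(gX, gX + 3 * N, 0.0);
  if (gPhi) std::fill(gPhi, gPhi + ne, 0.0);
  std::fill(w.Aedge.begin(), w.Aedge.end(), 0.0);

  // axial term
  if (gX) {
    for (int j = 0; j < ne; ++j) {
      if (rp.virt[j]) continue;
      double f = rp.alpha[j] * (w.len[j] / rp.elbar[j] - 1.0);
      addv(gX, j + 1, f * w.t[j]);
      addv(gX, j, -f * w.t[j]);
    }
  }

  for (int i = 1; i < N - 1; ++i) {
    if (!w.nodeok[i]) continue;
    double dk1 = w.kap1[i] - rp.kbar[2 * i], dk2 = w.kap2[i] - rp.kbar[2 * i + 1];
    double w1 = rp.bnode[i] / rp.lbar[i] * dk1;
    double w2 = rp.bnode[i] / rp.lbar[i] * dk2;
    // dE/d(kb)_i
    V3 g = 0.5 * w1 * (w.D2[i - 1] + w.D2[i]) - 0.5 * w2 * (w.D1[i - 1] + w.D1[i]);
    // frame-angle sensitivity of the bending term, per adjacent edge
    for (int j = i - 1; j <= i; ++j)
      w.Aedge[j] += -0.5 * w1 * dot(w.D1[j], w.kb[i]) - 0.5 * w2 * dot(w.D2[j], w.kb[i]);

    if (gX) {
      V3 ea = w.len[i - 1] * w.t[i - 1], eb = w.len[i] * w.t[i];
      double d = w.len[i - 1] * w.len[i] + dot(ea, eb);
      double kg = dot(w.kb[i], g);
      // d(kb)/dx_{i-1} = [2[eb]x + kb (lb ta + eb)^T]/d  (transposed action on g)
      V3 ga = (1.0 / d) * (-2.0 * cross(eb, g) + kg * (w.len[i] * w.t[i - 1] + eb));
      // d(kb)/dx_{i+1} = [2[ea]x - kb (la tb + ea)^T]/d
      V3 gb = (1.0 / d) * (-2.0 * cross(ea, g) - kg * (w.len[i - 1] * w.t[i] + ea));
      addv(gX, i - 1, ga);
      addv(gX, i + 1, gb);
      addv(gX, i, -1.0 * (ga + gb));
      // twist via reference-twist variation:
      // d(reftwist_i) = (kb_i/2) . (d e^{i-1}/l_{i-1} + d e^i/l_i)
      double Bi = rp.betanode[i] * w.tau[i] / rp.lbar[i];
      V3 ha = (0.5 * Bi / w.len[i - 1]) * w.kb[i];
      V3 hb = (0.5 * Bi / w.len[i]) * w.kb[i];
      addv(gX, i - 1, -1.0 * ha);
      addv(gX, i, ha - hb);
      addv(gX, i + 1, hb);
    }
  }

  if (gPhi) {
    for (int j = 0; j < ne; ++j) {
      double g = w.Aedge[j];
      if (j >= 1 && j <= N - 2 && w.nodeok[j])
        g += rp.betanode[j] * w.tau[j] / rp.lbar[j];
      if (j + 1 <= N - 2 && w.nodeok[j + 1])
        g -= rp.betanode[j + 1] * w.tau[j + 1] / rp.lbar[j + 1];
      gPhi[j] = g;
    }
  }
  return E;
}

static RodP make_rodp(int N, const NumericVector& elbar, const NumericVector& lbar,
                      const NumericMatrix& kbar, const NumericVector& alpha,
                      const NumericVector& bnode, const NumericVector& betanode,
                      const IntegerVector& virt) {
  RodP rp;
  rp.N = N; rp.ne = N - 1;
  if (elbar.size() != rp.ne || alpha.size() != rp.ne || virt.size() != rp.ne)
    stop("edge-quantity length mismatch");
  if (lbar.size() != N || bnode.size() != N || betanode.size() != N || kbar.nrow() != N)
    stop("node-quantity length mismatch");
  rp.elbar = elbar.begin(); rp.lbar = lbar.begin();
  rp.alpha = alpha.begin(); rp.bnode = bnode.begin(); rp.betanode = betanode.begin();
  rp.virt = virt.begin();
  // kbar comes in column-major; copy to row-major scratch held by caller is
  // avoided by transposing here into a static buffer.
  static thread_local std::vector<double> kb_rm;
  kb_rm.resize(2 * N);
  for (int i = 0; i < N; ++i) { kb_rm[2 * i] = kbar(i, 0); kb_rm[2 * i + 1] = kbar(i, 1); }
  rp.kbar = kb_rm.data();
  return rp;
}

// [[Rcpp::export]]
List cpp_rod_energy(NumericMatrix X, NumericVector phi, NumericMatrix U, NumericMatrix V,
                    NumericVector elbar, NumericVector lbar, NumericMatrix kbar,
                    NumericVector alpha, NumericVector bnode, NumericVector betanode,
                    IntegerVector virt) {
  int N = X.nrow();
  // matrices arrive column-major; repack row-major (x,y,z per point)
  std::vector<double> Xr(3 * N), Ur(3 * (N - 1)), Vr(3 * (N - 1));
  for (int i = 0; i < N; ++i) { Xr[3 * i] = X(i, 0); Xr[3 * i + 1] = X(i, 1); Xr[3 * i + 2] = X(i, 2); }
  for (int j = 0; j < N - 1; ++j) {
    Ur[3 * j] = U(j, 0); Ur[3 * j + 1] = U(j, 1); Ur[3 * j + 2] = U(j, 2);
    Vr[3 * j] = V(j, 0); Vr[3 * j + 1] = V(j, 1); Vr[3 * j + 2] = V(j, 2);
  }
  RodP rp = make_rodp(N, elbar, lbar, kbar, alpha, bnode, betanode, virt);
  RodWork w;
  double comps[3];
  double E = rod_energy_grad_core(rp, Xr.data(), phi.begin(), Ur.data(), Vr.data(),
                                  NULL, NULL, comps, w);
  NumericMatrix kap(N, 2);
  NumericVector tau(N);
  for (int i = 0; i < N; ++i) {
    bool ok = (i >= 1 && i <= N - 2 && w.nodeok[i]);
    kap(i, 0) = ok ? w.kap1[i] : NA_REAL;
    kap(i, 1) = ok ? w.kap2[i] : NA_REAL;
    tau[i] = ok ? w.tau[i] : NA_REAL;
  }
  return List::create(_["energy"] = E, _["axial"] = comps[0], _["bending"] = comps[1],
                      _["twist"] = comps[2], _["kappa"] = kap, _["tau"] = tau);
}

// [[Rcpp::export]]
List cpp_rod_energy_grad(NumericMatrix X, NumericVector phi, NumericMatrix U, NumericMatrix V,
                         NumericVector elbar, NumericVector lbar, NumericMatrix kbar,
                         NumericVector alpha, NumericVector bnode, NumericVector betanode,
                         IntegerVector virt) {
  int N = X.nrow();
  std::vector<double> Xr(3 * N), Ur(3 * (N - 1)), Vr(3 * (N - 1));
  for (int i = 0; i < N; ++i) { Xr[3 * i] = X(i, 0); Xr[3 * i + 1] = X(i, 1); Xr[3 * i + 2] = X(i, 2); }
  for (int j = 0; j < N - 1; ++j) {
    Ur[3 * j] = U(j, 0); Ur[3 * j + 1] = U(j, 1); Ur[3 * j + 2] = U(j, 2);
    Vr[3 * j] = V(j, 0); Vr[3 * j + 1] = V(j, 1); Vr[3 * j + 2] = V(j, 2);
  }
  RodP rp = make_rodp(N, elbar, lbar, kbar, alpha, bnode, betanode, virt);
  RodWork w;
  std::vector<double> gX(3 * N), gPhi(N - 1);
  double comps[3];
  double E = rod_energy_grad_core(rp, Xr.data(), phi.begin(), Ur.data(), Vr.data(),
                                  gX.data(), gPhi.data(), comps, w);
  NumericMatrix gXm(N, 3);
  for (int i = 0; i < N; ++i) { gXm(i, 0) = gX[3 * i]; gXm(i, 1) = gX[3 * i + 1]; gXm(i, 2) = gX[3 * i + 2]; }
  return List::create(_["energy"] = E, _["grad_x"] = gXm,
                      _["grad_phi"] = NumericVector(gPhi.begin(), gPhi.end()),
                      _["axial"] = comps[0], _["bending"] = comps[1], _["twist"] = comps[2]);
}

// Space-propagate a Bishop triad along the polyline from a seed U on the
// first edge.  Virtual edges are crossed by plain parallel transport so each
// coil's chain starts from a smoothly transported seed.
// [[Rcpp::export]]
List cpp_propagate_bishop(NumericMatrix X, NumericVector u0) {
  int N = X.nrow(), ne = N - 1;
  NumericMatrix U(ne, 3), V(ne, 3);
  std::vector<V3> t(ne);
  for (int j = 0; j < ne; ++j) {
    V3 e = V3(X(j + 1, 0) - X(j, 0), X(j + 1, 1) - X(j, 1), X(j + 1, 2) - X(j, 2));
    double l = norm(e);
    if (!(l > 0.0)) stop("zero-length edge %d", j);
    t[j] = (1.0 / l) * e;
  }
  V3 u(u0[0], u0[1], u0[2]);
  u = u - dot(u, t[0]) * t[0];
  if (norm(u) < 1e-12) stop("seed frame vector parallel to first edge");
  u = normalize(u);
  for (int j = 0; j < ne; ++j) {
    if (j > 0) {
      u = par_transport(t[j - 1], t[j], u);
      u = normalize(u - dot(u, t[j]) * t[j]);
    }
    V3 v = cross(t[j], u);
    U(j, 0) = u.x; U(j, 1) = u.y; U(j, 2) = u.z;
    V(j, 0) = v.x; V(j, 1) = v.y; V(j, 2) = v.z;
  }
  return List::create(_["U"] = U, _["V"] = V);
}

// Time-parallel transport of per-edge frames from an old configuration to a
// new one (used by the finite-difference oracle and the time stepper).
// [[Rcpp::export]]
List cpp_transport_frames(NumericMatrix Xold, NumericMatrix Xnew,
                          NumericMatrix U, NumericMatrix V) {
  int N = Xold.nrow(), ne = N - 1;
  NumericMatrix U2(ne, 3), V2(ne, 3);
  for (int j = 0; j < ne; ++j) {
    V3 e0 = V3(Xold(j + 1, 0) - Xold(j, 0), Xold(j + 1, 1) - Xold(j, 1), Xold(j + 1, 2) - Xold(j, 2));
    V3 e1 = V3(Xnew(j + 1, 0) - Xnew(j, 0), Xnew(j + 1, 1) - Xnew(j, 1), Xnew(j + 1, 2) - Xnew(j, 2));
    V3 t0 = normalize(e0), t1 = normalize(e1);
    V3 u = par_transport(t0, t1, V3(U(j, 0), U(j, 1), U(j, 2)));
    u = normalize(u - dot(u, t1) * t1);
    V3 v = cross(t1, u);
    U2(j, 0) = u.x; U2(j, 1) = u.y; U2(j, 2) = u.z;
    V2(j, 0) = v.x; V2(j, 1) = v.y; V2(j, 2) = v.z;
  }
  return List::create(_["U"] = U2, _["V"] = V2);
}

// hook used by the deployment integrator (deploy.cpp)
double rod_energy_grad_raw(int N, const double* X, const double* phi,
                           const double* U, const double* V,
                           const double* elbar, const double* lbar, const double* kbar,
                           const double* alpha, const double* bnode, const double* betanode,
                           const int* virt, double* gX, double* gPhi, double* comps,
                           bool zero_reftwist) {
  RodP rp; rp.N = N; rp.ne = N - 1;
  rp.elbar = elbar; rp.lbar = lbar; rp.kbar = kbar; rp.alpha = alpha;
  rp.bnode = bnode; rp.betanode = betanode; rp.virt = virt;
  static thread_local RodWork w;
  return rod_energy_grad_core(rp, X, phi, U, V, gX, gPhi, comps, w, zero_reftwist);
}
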