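#include "common.h"
#include "contact.h"
using namespace Rcpp;

// Time integration of the coil ODE system with catheter-insertion boundary
// conditions.  Symplectic Euler: velocities first from forces at t_n, then
// positions with the new velocities; edge angles follow the damped gradient
// flow (rotational inertia is zero by model choice).  Nodes still inside the
// micro-catheter are kinematic: their velocity is the insertion speed along
// the local catheter tangent and their position is the spline point at their
// current arc coordinate.
//
// Two-phase wall geometry: steps [0, n_insert) use the neck-cut dome mesh
// with the catheter tube as an additional obstacle; the remaining steps use
// the full vessel mesh with the catheter retracted.

struct CathTable {
  // arc-length sampled spline: position and unit tangent at s = k * ds
  std::vector<V3> P, T;
  double ds = 0.0, S = 0.0;  // sample spacing, total arc length
  bool active = false;
  V3 pos(double s) const {
    if (s <= 0.0) return P.front() + s * T.front();
    if (s >= S) return P.back() + (s - S) * T.back();
    double u = s / ds;
    int k = std::min((int)P.size() - 2, (int)u);
    double f = u - k;
    return (1.0 - f) * P[k] + f * P[k + 1];
  }
  V3 tan(double s) const {
    if (s <= 0.0) return T.front();
    if (s >= S) return T.back();
    double u = s / ds;
    int k = std::min((int)T.size() - 2, (int)u);
    double f = u - k;
    return normalize((1.0 - f) * T[k] + f * T[k + 1]);
  }
};

static void repack(const NumericMatrix& M, std::vector<double>& out) {
  int n = M.nrow();
  out.resize(3 * n);
  for (int i = 0; i < n; ++i) { out[3 * i] = M(i, 0); out[3 * i + 1] = M(i, 1); out[3 * i + 2] = M(i, 2); }
}

// [[Rcpp::export]]
List cpp_run_deployment(List rod, List cathlist, List walls, NumericVector cparams,
                        bool literal_wall, List cfg) {
  // --- unpack rod state -------------------------------------------------
  NumericMatrix X0 = rod["x"], U0 = rod["u"], V0 = rod["v"], Vel0 = rod["vel"];
  NumericVector phi0 = rod["phi"];
  NumericVector elbar = rod["rest_edge_lengths"], lbar = rod["voronoi"];
  NumericMatrix kbarM = rod["kbar"];
  NumericVector alpha = rod["alpha"], bnode = rod["b"], betanode = rod["beta"];
  IntegerVector virtR = rod["virtual_edge"];
  NumericVector massR = rod["mass"];
  IntegerVector clampR = rod["clamp"];
  NumericVector arcR = rod["arc"];  // rest arc coordinate of each node from the leading tip

  const int N = X0.nrow(), ne = N - 1;
  std::vector<double> X, U, Vf, vel, phi(phi0.begin(), phi0.end());
  repack(X0, X); repack(U0, U); repack(V0, Vf); repack(Vel0, vel);
  std::vector<double> kbar(2 * N);
  for (int i = 0; i < N; ++i) { kbar[2 * i] = kbarM(i, 0); kbar[2 * i + 1] = kbarM(i, 1); }
  std::vector<int> virt(virtR.begin(), virtR.end());
  std::vector<int> clampv(clampR.begin(), clampR.end());
  std::vector<double> mass(massR.begin(), massR.end());
  std::vector<double> arc(arcR.begin(), arcR.end());

  // --- config -----------------------------------------------------------
  const double dt = as<double>(cfg["dt"]);
  const double vpush = as<double>(cfg["v_push"]);
  const long n_insert = as<double>(cfg["n_insert"]);
  const long n_post = as<double>(cfg["n_post"]);
  const long record_every = std::max(1.0, as<double>(cfg["record_every"]));
  const double eta_x = as<double>(cfg["eta_x"]), eta_phi = as<double>(cfg["eta_phi"]);
  NumericVector grav = cfg["gravity"];
  const V3 g(grav[0], grav[1], grav[2]);
  const double s_head0 = as<double>(cfg["s_head"]);  // arc position of node 0 at t = 0
  const bool contact_on = cfg.containsElementNamed("contact") ? as<bool>(cfg["contact"]) : true;

  ContactParams prm;
  prm.k_sc = cparams[0]; prm.g_sc = cparams[1]; prm.k_w = cparams[2]; prm.g_w = cparams[3];
  prm.mu_cc = cparams[4]; prm.mu_slip_cw = cparams[5]; prm.mu_stick_cw = cparams[6];
  prm.v_eps = cparams[7]; prm.D2 = cparams[8];
  prm.literal_wall = literal_wall;
  double restlen_ref = 0.0;
  for (int j = 0; j < ne; ++j) if (!virt[j]) restlen_ref = std::max(restlen_ref, elbar[j]);

  // --- catheter ---------------------------------------------------------
  CathTable cath;
  WallMesh cathmesh;
  bool use_cath = as<bool>(cathlist["active"]);
  if (use_cath) {
    NumericMatrix CP = cathlist["points"], CT = cathlist["tangents"];
    cath.ds = as<double>(cathlist["ds"]); cath.S = as<double>(cathlist["arc_length"]);
    cath.active = true;
    cath.P.resize(CP.nrow()); cath.T.resize(CT.nrow());
    for (int k = 0; k < CP.nrow(); ++k) {
      cath.P[k] = V3(CP(k, 0), CP(k, 1), CP(k, 2));
      cath.T[k] = normalize(V3(CT(k, 0), CT(k, 1), CT(k, 2)));
    }
    if (cathlist.containsElementNamed("tube_vertices")) {
      NumericMatrix tv = cathlist["tube_vertices"];
      IntegerMatrix tf = cathlist["tube_faces"];
      if (tv.nrow() > 0) cathmesh.init(tv, tf);
    }
  }

  // --- walls ------------------------------------------------------------
  WallMesh wall1, wall2;
  bool has_w1 = false, has_w2 = false;
  if (walls.containsElementNamed("dome_vertices")) {
    NumericMatrix wv = walls["dome_vertices"]; IntegerMatrix wf = walls["dome_faces"];
    if (wv.nrow() > 0) { wall1.init(wv, wf); has_w1 = true; }
  }
  if (walls.containsElementNamed("vessel_vertices")) {
    NumericMatrix wv = walls["vessel_vertices"]; IntegerMatrix wf = walls["vessel_faces"];
    if (wv.nrow() > 0) { wall2.init(wv, wf); has_w2 = true; }
  }
  if (!has_w2 && has_w1) { has_w2 = true; }  // fall back to phase-1 wall

  // --- workspaces -------------------------------------------------------
  std::vector<double> gX(3 * N), gPhi(ne), Fel(3 * N), Fext(3 * N), comps(3);
  std::vector<int> active(N, 1), release(N, -1), edge_incl(ne, 1);
  std::vector<double> st_sum(ne, 0.0), st_sumsq(ne, 0.0);
  std::vector<long> st_count(ne, 0);
  CoilContactWork cw;
  ContactDiag diag;
  double run_fric_ratio = 0.0, run_pair_asym = 0.0, run_max_pen = 0.0;

  std::vector<double> rec_step, rec_time, rec_ax, rec_bend, rec_tw, rec_kin,
      rec_ncc, rec_ncw, rec_pen, rec_ins, rec_maxstretch;
  List traj;
  std::vector<long> traj_steps;
  std::vector<NumericMatrix> traj_frames;

  const long n_total = n_insert + n_post;
  long aborted_at = -1;

  // helper: record a sample
  auto snapshot = [&](long n, double Eax, double Ebend, double Etw, int ncc, int ncw,
                      double pen, double inserted) {
    double kin = 0.0, mst = 0.0;
    for (int i = 0; i < N; ++i) {
      V3 v = getv(vel.data(), i);
      kin += 0.5 * mass[i] * dot(v, v);
    }
    for (int j = 0; j < ne; ++j) {
      if (virt[j]) continue;
      V3 e = getv(X.data(), j + 1) - getv(X.data(), j);
      mst = std::max(mst, std::fabs(norm(e) / elbar[j] - 1.0));
    }
    rec_step.push_back((double)n); rec_time.push_back(n * dt);
    rec_ax.push_back(Eax); rec_bend.push_back(Ebend); rec_tw.push_back(Etw);
    rec_kin.push_back(kin); rec_ncc.push_back(ncc); rec_ncw.push_back(ncw);
    rec_pen.push_back(pen); rec_ins.push_back(inserted); rec_maxstretch.push_back(mst);
    NumericMatrix fr(N, 3);
    for (int i = 0; i < N; ++i) { fr(i, 0) = X[3 * i]; fr(i, 1) = X[3 * i + 1]; fr(i, 2) = X[3 * i + 2]; }
    traj_frames.push_back(fr);
    traj_steps.push_back(n);
  };

  for (long n = 0; n < n_total; ++n) {
    bool insertion_phase = n < n_insert;
    const WallMesh* wallp = insertion_phase ? (has_w1 ? &wall1 : NULL)
                                            : (has_w2 ? &wall2 : (has_w1 ? &wall1 : NULL));
    const WallMesh* cathp = (insertion_phase && cathmesh.nf > 0) ? &cathmesh : NULL;

    // kinematic set: nodes whose arc position is before the catheter tip
    double shead = s_head0 + vpush * dt * n;
    int n_kin = 0;
    if (use_cath && insertion_phase) {
      for (int i = 0; i < N; ++i) {
        double si = shead - arc[i];
        bool inside = si < cath.S;
        if (!inside && release[i] < 0) release[i] = (int)n;
        active[i] = inside ? 0 : 1;
        if (inside) n_kin++;
      }
    } else {
      for (int i = 0; i < N; ++i) {
        if (release[i] < 0) release[i] = (int)n;
        active[i] = 1;
      }
    }
    for (int i = 0; i < N; ++i) if (clampv[i]) active[i] = 0;
    // contact geometry: released edges plus the two edges about to emerge
    // from the catheter; the rest are parked inside the tube
    if (use_cath && insertion_phase) {
      int kfirst = N;  // first node still inside
      for (int i = 0; i < N; ++i) if (release[i] < 0) { kfirst = i; break; }
      for (int j = 0; j < ne; ++j) edge_incl[j] = (j <= kfirst + 1) ? 1 : 0;
    } else {
      std::fill(edge_incl.begin(), edge_incl.end(), 1);
    }

    // forces
    double E = rod_energy_grad_raw(N, X.data(), phi.data(), U.data(), Vf.data(),
                                   elbar.begin(), lbar.begin(), kbar.data(),
                                   alpha.begin(), bnode.begin(), betanode.begin(),
                                   virt.data(), gX.data(), gPhi.data(), comps.data(),
                                   true /* frames are freshly propagated Bishop */);
    (void)E;
    for (int i = 0; i < 3 * N; ++i) Fel[i] = -gX[i];
    if (contact_on) {
      external_forces_core(N, X.data(), vel.data(), Fel.data(), virt.data(), active.data(),
                           prm, wallp, cathp, restlen_ref, Fext.data(), diag, cw,
                           edge_incl.data());
    } else {
      std::fill(Fext.begin(), Fext.end(), 0.0);
      diag = ContactDiag();
    }
    run_fric_ratio = std::max(run_fric_ratio, diag.max_fric_ratio);
    run_pair_asym = std::max(run_pair_asym, diag.max_pair_asym);
    run_max_pen = std::max(run_max_pen, diag.max_pen);

    // velocity + position update
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      if (clampv[i]) { setv(vel.data(), i, V3()); continue; }
      if (!active[i]) {
        double si = shead - arc[i];
        V3 vi = vpush * cath.tan(si);
        setv(vel.data(), i, vi);
        continue;
      }
      V3 v = getv(vel.data(), i);
      V3 F = getv(Fel.data(), i) + getv(Fext.data(), i) + mass[i] * g - eta_x * v;
      v += (dt / mass[i]) * F;
      if (!std::isfinite(v.x) || !std::isfinite(v.y) || !std::isfinite(v.z)) bad = true;
      setv(vel.data(), i, v);
    }
    if (bad) { aborted_at = n; break; }
    double shead_next = s_head0 + vpush * dt * (n + 1);
    for (int i = 0; i < N; ++i) {
      if (clampv[i]) continue;
      if (!active[i]) {
        setv(X.data(), i, cath.pos(shead_next - arc[i]));
      } else {
        V3 x = getv(X.data(), i) + dt * getv(vel.data(), i);
        setv(X.data(), i, x);
      }
    }

    // edge-angle gradient flow
    for (int j = 0; j < ne; ++j)
      if (!virt[j]) phi[j] -= dt / eta_phi * gPhi[j];

    // frames: time-parallel transport, then re-propagate the Bishop frame
    // and fold the holonomy correction back into phi so the material
    // directors are preserved
    {
      V3 tprev_new;
      V3 u_b;  // propagated Bishop u
      for (int j = 0; j < ne; ++j) {
        V3 e = getv(X.data(), j + 1) - getv(X.data(), j);
        double l = norm(e);
        if (!(l > 0.0) || !std::isfinite(l)) { bad = true; break; }
        V3 tnew = (1.0 / l) * e;
        V3 uold = getv(U.data(), j);
        // stored frames are adapted to the pre-update tangent; recover it
        // from the stored U,V triad: t_old = U x V
        V3 vold = getv(Vf.data(), j);
        V3 told = cross(uold, vold);
        V3 ut = par_transport(told, tnew, uold);
        ut = normalize(ut - dot(ut, tnew) * tnew);
        if (j == 0) {
          u_b = ut;
        } else {
          u_b = par_transport(tprev_new, tnew, u_b);
          u_b = normalize(u_b - dot(u_b, tnew) * tnew);
        }
        double corr = signed_angle(u_b, ut, tnew);
        phi[j] = wrap_angle(phi[j] + corr);
        setv(U.data(), j, u_b);
        setv(Vf.data(), j, cross(tnew, u_b));
        tprev_new = tnew;
      }
      if (bad) { aborted_at = n; break; }
    }

    // stretch bookkeeping for fully released edges
    for (int j = 0; j < ne; ++j) {
      if (virt[j]) continue;
      if (release[j] < 0 || release[j + 1] < 0) continue;
      V3 e = getv(X.data(), j + 1) - getv(X.data(), j);
      double rel = std::fabs(norm(e) / elbar[j] - 1.0);
      st_sum[j] += rel; st_sumsq[j] += rel * rel; st_count[j] += 1;
    }

    if (n % record_every == 0 || n == n_total - 1) {
      double inserted = use_cath ? std::min(std::max(shead_next - cath.S, 0.0),
                                            arc[N - 1] + (shead_next - cath.S > arc[N - 1] ? 0.0 : 0.0))
                                 : 0.0;
      if (use_cath) inserted = std::min(shead_next - cath.S, arc[N - 1]);
      snapshot(n, comps[0], comps[1], comps[2], diag.n_cc, diag.n_cw, diag.max_pen,
               std::max(0.0, inserted));
    }
    if (n % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  // --- pack results -----------------------------------------------------
  NumericMatrix Xo(N, 3), Velo(N, 3), Uo(ne, 3), Vo(ne, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { Xo(i, d) = X[3 * i + d]; Velo(i, d) = vel[3 * i + d]; }
  for (int j = 0; j < ne; ++j)
    for (int d = 0; d < 3; ++d) { Uo(j, d) = U[3 * j + d]; Vo(j, d) = Vf[3 * j + d]; }

  List trajl(traj_frames.size());
  for (size_t k = 0; k < traj_frames.size(); ++k) trajl[k] = traj_frames[k];

  DataFrame series = DataFrame::create(
      _["step"] = rec_step, _["time"] = rec_time, _["axial_energy"] = rec_ax,
      _["bending_energy"] = rec_bend, _["twist_energy"] = rec_tw, _["kinetic_energy"] = rec_kin,
      _["coil_contacts"] = rec_ncc, _["wall_contacts"] = rec_ncw,
      _["max_penetration"] = rec_pen, _["inserted_length"] = rec_ins,
      _["max_stretch"] = rec_maxstretch);

  return List::create(
      _["x"] = Xo, _["vel"] = Velo, _["u"] = Uo, _["v"] = Vo,
      _["phi"] = NumericVector(phi.begin(), phi.end()),
      _["release_step"] = IntegerVector(release.begin(), release.end()),
      _["stretch_sum"] = NumericVector(st_sum.begin(), st_sum.end()),
      _["stretch_sumsq"] = NumericVector(st_sumsq.begin(), st_sumsq.end()),
      _["stretch_count"] = NumericVector(st_count.begin(), st_count.end()),
      _["series"] = series,
      _["trajectory"] = trajl,
      _["trajectory_steps"] = NumericVector(traj_steps.begin(), traj_steps.end()),
      _["max_friction_ratio"] = run_fric_ratio,
      _["max_pair_asymmetry"] = run_pair_asym,
      _["max_penetration"] = run_max_pen,
      _["n_steps"] = (double)n_total,
      _["aborted_at"] = (double)aborted_at);
}
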