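#pragma once
#include "common.h"

// Octree over points with per-item radii (triangle enclosing spheres or
// edge centers).  query(q, r) returns a guaranteed superset of all items i
// with ||q - p_i|| <= r + rad_i.
struct Octree {
  struct Node {
    V3 c;
    double half, maxrad;
    int start, count;
    int child[8];
    bool leaf;
  };
  std::vector<Node> nodes;
  std::vector<int> perm;
  const std::vector<V3>* pts_;
  const std::vector<double>* rad_;
  int leafcap, maxdepth;
  mutable std::vector<int> hits_scratch;

  void build(const std::vector<V3>& pts, const std::vector<double>& rad,
             int leafcap_, int maxdepth_);
  int build_node(const V3& c, double half, int start, int count, int depth);
  void query(const V3& q, double radius, std::vector<int>& out) const;
  void query_node(int id, const V3& q, double radius, std::vector<int>& out) const;
};

struct WallMesh {
  int nf = 0;
  std::vector<V3> vert, fnormal, center;
  std::vector<int> f0, f1, f2;
  std::vector<double> rst;
  Octree tree;
  void init(const Rcpp::NumericMatrix& Vm, const Rcpp::IntegerMatrix& Fm);
  bool node_contact(const V3& p, int k, double reach, bool literal,
                    double* dist, V3* cp, V3* pushdir) const;
};

struct ContactParams {
  double k_sc, g_sc, k_w, g_w, mu_cc, mu_slip_cw, mu_stick_cw, v_eps, D2;
  bool literal_wall;
};

struct ContactDiag {
  int n_cc = 0, n_cw = 0;
  double max_pen = 0.0, max_fric_ratio = 0.0, max_pair_asym = 0.0;
};

struct CoilContactWork {
  std::vector<V3> centers;
  std::vector<double> rad0, Fcc;
  Octree tree;
  std::vector<int> hits;
  std::vector<std::pair<int, int> > pairs;
};

void seg_seg_dist(const V3& p1, const V3& q1, const V3& p2, const V3& q2,
                  double* s_out, double* t_out, V3* c1_out, V3* c2_out, double* dist);
void coil_candidates(int N, const double* X, const int* virt, double bound,
                     CoilContactWork& w, std::vector<std::pair<int, int> >& pairs,
                     const int* edge_incl = 0);
void external_forces_core(int N, const double* X, const double* vel, const double* Felastic,
                          const int* virt, const int* active,
                          const ContactParams& prm,
                          const WallMesh* wall, const WallMesh* cath,
                          double restlen_ref,
                          double* Fext, ContactDiag& diag, CoilContactWork& w,
                          const int* edge_incl = 0);
double rod_energy_grad_raw(int N, const double* X, const double* phi,
                           const double* U, const double* V,
                           const double* elbar, const double* lbar, const double* kbar,
                           const double* alpha, const double* bnode, const double* betanode,
                           const int* virt, double* gX, double* gPhi, double* comps,
                           bool zero_reftwist = false);
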