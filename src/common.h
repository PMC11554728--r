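#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstring>

// Minimal 3-vector used throughout the compiled core.  All geometry is in a
// consistent (mm, kg, s) unit system: forces in mN, energies in uJ (mN*mm),
// stiffnesses b, beta in mN*mm^2, pressures in kPa.
struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
inline V3 operator*(const V3& a, double s) { return s * a; }
inline V3& operator+=(V3& a, const V3& b) { a.x += b.x; a.y += b.y; a.z += b.z; return a; }
inline V3& operator-=(V3& a, const V3& b) { a.x -= b.x; a.y -= b.y; a.z -= b.z; return a; }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
inline V3 normalize(const V3& a) {
  double n = norm(a);
  return (n > 0.0) ? (1.0 / n) * a : V3(0, 0, 0);
}

inline V3 getv(const double* p, int i) { return V3(p[3 * i], p[3 * i + 1], p[3 * i + 2]); }
inline void setv(double* p, int i, const V3& v) { p[3 * i] = v.x; p[3 * i + 1] = v.y; p[3 * i + 2] = v.z; }
inline void addv(double* p, int i, const V3& v) { p[3 * i] += v.x; p[3 * i + 1] += v.y; p[3 * i + 2] += v.z; }

// Wrap an angle to (-pi, pi].
inline double wrap_angle(double a) {
  const double TWO_PI = 2.0 * M_PI;
  a -= TWO_PI * std::floor(a / TWO_PI);   // now in [0, 2*pi)
  if (a > M_PI) a -= TWO_PI;
  return a;
}

// Parallel transport (Rodrigues rotation taking unit t0 to unit t1) applied
// to v.  Antiparallel tangents are a modeling error handled by callers; here
// we guard the denominator.
inline V3 par_transport(const V3& t0, const V3& t1, const V3& v) {
  V3 b = cross(t0, t1);
  double c = dot(t0, t1);
  if (c < -1.0 + 1e-12) Rcpp::stop("degenerate turn: antiparallel tangents in parallel transport");
  // R v = v + b x v + (b x (b x v)) / (1 + c)
  V3 bv = cross(b, v);
  V3 bbv = cross(b, bv);
  return v + bv + (1.0 / (1.0 + c)) * bbv;
}

// Signed angle rotating a to b about unit axis t (a, b assumed orthogonal-ish to t).
inline double signed_angle(const V3& a, const V3& b, const V3& t) {
  return std::atan2(dot(cross(a, b), t), dot(a, b));
}

// Closest point on triangle (p0,p1,p2) to point q.  Returns point; sets
// feature code: 0 face, 1/2/3 edge (p0p1, p1p2, p2p0), 4/5/6 vertex p0/p1/p2.
V3 closest_point_triangle(const V3& q, const V3& p0, const V3& p1, const V3& p2, int* feature);
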