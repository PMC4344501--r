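#ifndef SUPERCOILR_RING_H
#define SUPERCOILR_RING_H

#include <cmath>
#include <algorithm>

// Minimal 3-vector helpers on raw double[3].  All simulation code works in
// reduced units: bead diameter sigma_LJ = 1, kT = epsilon_0 = 1.

namespace scr {

inline void vset(double *a, double x, double y, double z) {
  a[0] = x; a[1] = y; a[2] = z;
}
inline void vcopy(double *a, const double *b) {
  a[0] = b[0]; a[1] = b[1]; a[2] = b[2];
}
inline void vsub(double *out, const double *a, const double *b) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline void vadd(double *out, const double *a, const double *b) {
  out[0] = a[0] + b[0]; out[1] = a[1] + b[1]; out[2] = a[2] + b[2];
}
inline void vaxpy(double *y, double alpha, const double *x) {
  y[0] += alpha * x[0]; y[1] += alpha * x[1]; y[2] += alpha * x[2];
}
inline void vscale(double *a, double s) {
  a[0] *= s; a[1] *= s; a[2] *= s;
}
inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void vcross(double *out, const double *a, const double *b) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double vnorm(const double *a) { return std::sqrt(vdot(a, a)); }
inline double vnormalize(double *a) {
  double n = vnorm(a);
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
  return n;
}

// minimum-image displacement component for cubic box of edge L (L <= 0: none)
inline double min_image(double d, double L) {
  if (L > 0) d -= L * std::round(d / L);
  return d;
}
inline void vsub_mi(double *out, const double *a, const double *b, double L) {
  out[0] = min_image(a[0] - b[0], L);
  out[1] = min_image(a[1] - b[1], L);
  out[2] = min_image(a[2] - b[2], L);
}

// Rodrigues rotation of v about unit axis k by angle theta (in place).
inline void vrotate(double *v, const double *k, double theta) {
  double c = std::cos(theta), s = std::sin(theta);
  double kxv[3];
  vcross(kxv, k, v);
  double kd = vdot(k, v);
  for (int d = 0; d < 3; ++d)
    v[d] = v[d] * c + kxv[d] * s + k[d] * kd * (1.0 - c);
}

// Parallel transport of vector v from unit tangent a to unit tangent b:
// rotate about axis a x b by the angle between a and b (Rodrigues with
// sin/cos taken directly from the cross and dot products; no
// transcendentals).  Near-parallel tangents: identity.  Antiparallel
// tangents are geometrically degenerate; caller must guard.
inline void transport(double *v, const double *a, const double *b) {
  double ax[3];
  vcross(ax, a, b);
  double s = vnorm(ax);
  double c = vdot(a, b);
  if (s < 1e-14) return;        // parallel (c ~ +1) or caller-guarded c ~ -1
  ax[0] /= s; ax[1] /= s; ax[2] /= s;
  double kxv[3];
  vcross(kxv, ax, v);
  double kd = vdot(ax, v);
  for (int d = 0; d < 3; ++d)
    v[d] = v[d] * c + kxv[d] * s + ax[d] * kd * (1.0 - c);
}

// Signed angle from a to b about unit axis u (a, b not parallel to u).
inline double signed_angle(const double *a, const double *b, const double *u) {
  double cx[3];
  vcross(cx, a, b);
  return std::atan2(vdot(cx, u), vdot(a, b));
}

// Signed solid angle of the spherical triangle spanned by unit vectors
// x, y, z (Van Oosterom & Strackee): numerically stable near zero, exactly
// zero for coplanar configurations.
inline double solid_tri(const double *x, const double *y, const double *z) {
  double yz[3];
  vcross(yz, y, z);
  double det = vdot(x, yz);
  double denom = 1.0 + vdot(x, y) + vdot(y, z) + vdot(z, x);
  return 2.0 * std::atan2(det, denom);
}

// Exact Gauss-integral contribution (solid angle / 4pi) of a directed
// segment pair (p1->p2, p3->p4): signed solid angle of the spherical
// quadrilateral of the four connecting directions, split into two
// triangles.  Returns 0 for degenerate (touching / zero-length)
// configurations.
inline double writhe_pair(const double *p1, const double *p2,
                          const double *p3, const double *p4) {
  double r13[3], r14[3], r23[3], r24[3];
  vsub(r13, p3, p1);
  vsub(r14, p4, p1);
  vsub(r23, p3, p2);
  vsub(r24, p4, p2);
  double l13 = vnormalize(r13), l14 = vnormalize(r14),
         l23 = vnormalize(r23), l24 = vnormalize(r24);
  if (l13 < 1e-14 || l14 < 1e-14 || l23 < 1e-14 || l24 < 1e-14) return 0.0;
  // oriented quadrilateral r13 -> r14 -> r24 -> r23 on the unit sphere
  double omega = solid_tri(r13, r14, r24) + solid_tri(r13, r24, r23);
  return -omega / (4.0 * M_PI);
}

// Writhe of a closed polygon with n vertices stored row-major (n x 3,
// as pos[i*3 + d]).  Sum over unordered non-adjacent segment pairs, doubled.
inline double writhe_polygon(const double *pos, int n) {
  double wr = 0.0;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j2 == i) continue;    // closing segment adjacent to segment 0
      wr += writhe_pair(pos + 3 * i, pos + 3 * i2, pos + 3 * j, pos + 3 * j2);
    }
  }
  return 2.0 * wr;
}

}  // namespace scr

#endif
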