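#ifndef SUPERCOILR_FORCES_H
#define SUPERCOILR_FORCES_H

#include "ring.h"

// Per-interaction force/energy kernels.  Shared by the one-shot energy/force
// entry points and by the Brownian-dynamics integrator so both paths evaluate
// the identical Hamiltonian.
//
// Energy terms (reduced units, sigma = 1, kT = eps0 = 1):
//   bond      U = (k/2) (|e| - r0)^2 over consecutive beads
//   bend      U = kappa (1 - cos theta) per interior junction
//   twist     U = (kt/2) phi^2 per junction, phi the ribbon twist angle
//   repulsion U = 4 eps [r^-12 - r^-6], r < rcut (= 1: vanishes at cutoff)
//   EP well   U = 4 eps [r^-12 - r^-6] - shift, r < rcut, shifted to 0 there

namespace scr {

// Repulsion diverges as r -> 0; beyond this force the pair force is capped
// and the configuration flagged.  The cap corresponds to overlaps deeper
// than r ~ 0.85 sigma (U ~ 20 kT, Boltzmann-negligible at equilibrium), so
// it only acts on warm-up transients, where it keeps the Euler-Maruyama
// displacement bounded instead of aborting the run.
constexpr double REP_FORCE_CAP = 200.0;

inline void accum_bond(const double *x, double *F, int i, int j,
                       double k, double r0, double *U) {
  double e[3];
  vsub(e, x + 3 * j, x + 3 * i);
  double r = vnorm(e);
  if (r <= 0) return;
  double d = r - r0;
  *U += 0.5 * k * d * d;
  double fmag = -k * d / r;      // force on j along e
  vaxpy(F + 3 * j, fmag, e);
  vaxpy(F + 3 * i, -fmag, e);
}

// Bending at vertex b between edges a->b and b->c.
inline void accum_bend(const double *x, double *F, int a, int b, int c,
                       double kappa, double *U) {
  double e1[3], e2[3];
  vsub(e1, x + 3 * b, x + 3 * a);
  vsub(e2, x + 3 * c, x + 3 * b);
  double l1 = vnorm(e1), l2 = vnorm(e2);
  if (l1 <= 0 || l2 <= 0) return;
  double u1[3] = {e1[0] / l1, e1[1] / l1, e1[2] / l1};
  double u2[3] = {e2[0] / l2, e2[1] / l2, e2[2] / l2};
  double ct = vdot(u1, u2);
  *U += kappa * (1.0 - ct);
  // g1 = d(cos)/d e1, g2 = d(cos)/d e2
  double g1[3], g2[3];
  for (int d = 0; d < 3; ++d) {
    g1[d] = (u2[d] - ct * u1[d]) / l1;
    g2[d] = (u1[d] - ct * u2[d]) / l2;
  }
  // F = +kappa * d(cos)/dx
  vaxpy(F + 3 * a, -kappa, g1);
  for (int d = 0; d < 3; ++d) F[3 * b + d] += kappa * (g1[d] - g2[d]);
  vaxpy(F + 3 * c, kappa, g2);
}

// Twist gradient at a junction (vertex b between edges a->b->c) with twist
// angle phi.  Uses the discrete-rods curvature-binormal expression for the
// positional gradient of the parallel-transport twist.
inline void accum_twist_force(const double *x, double *F, int a, int b, int c,
                              double kt, double phi, double *U) {
  double e1[3], e2[3];
  vsub(e1, x + 3 * b, x + 3 * a);
  vsub(e2, x + 3 * c, x + 3 * b);
  double l1 = vnorm(e1), l2 = vnorm(e2);
  if (l1 <= 0 || l2 <= 0) return;
  *U += 0.5 * kt * phi * phi;
  double denom = l1 * l2 + vdot(e1, e2);
  if (denom < 1e-12) return;     // ~180 degree bend, guarded upstream
  double kb[3];
  vcross(kb, e1, e2);
  vscale(kb, 2.0 / denom);
  // dphi/dx_a = -kb/(2 l1); dphi/dx_c = kb/(2 l2); dphi/dx_b = -(sum)
  double coef = -kt * phi;       // F = -dU/dphi * dphi/dx
  double fa[3], fc[3];
  for (int d = 0; d < 3; ++d) {
    fa[d] = coef * (-kb[d] / (2.0 * l1));
    fc[d] = coef * (kb[d] / (2.0 * l2));
  }
  for (int d = 0; d < 3; ++d) {
    F[3 * a + d] += fa[d];
    F[3 * c + d] += fc[d];
    F[3 * b + d] -= fa[d] + fc[d];
  }
}

// Purely repulsive truncated LJ between beads i, j under minimum image.
// Returns true if the force had to be capped.
inline bool accum_pair_rep(const double *x, double *F, int i, int j,
                           double box, double eps, double rcut, double *U) {
  double d[3];
  vsub_mi(d, x + 3 * i, x + 3 * j, box);
  double r2 = vdot(d, d);
  if (r2 >= rcut * rcut) return false;
  bool capped = false;
  double r2min = 1e-4;           // r = 0.01 sigma: cap zone
  if (r2 < r2min) { r2 = r2min; capped = true; }
  double inv2 = 1.0 / r2;
  double inv6 = inv2 * inv2 * inv2;
  *U += 4.0 * eps * inv6 * (inv6 - 1.0);
  double fr = 24.0 * eps * inv6 * (2.0 * inv6 - 1.0) * inv2;  // F/r on i
  if (fr > REP_FORCE_CAP) { fr = REP_FORCE_CAP; capped = true; }
  vaxpy(F + 3 * i, fr, d);
  vaxpy(F + 3 * j, -fr, d);
  return capped;
}

inline double ep_shift(double eps, double rcut) {
  double inv6 = 1.0 / (rcut * rcut * rcut * rcut * rcut * rcut);
  return 4.0 * eps * inv6 * (inv6 - 1.0);
}

// Attractive truncated-and-shifted LJ for the enhancer-promoter pair.
inline void accum_pair_ep(const double *x, double *F, int i, int j,
                          double box, double eps, double rcut, double *U) {
  double d[3];
  vsub_mi(d, x + 3 * i, x + 3 * j, box);
  double r2 = vdot(d, d);
  if (r2 >= rcut * rcut) return;
  if (r2 < 1e-4) r2 = 1e-4;
  double inv2 = 1.0 / r2;
  double inv6 = inv2 * inv2 * inv2;
  *U += 4.0 * eps * inv6 * (inv6 - 1.0) - ep_shift(eps, rcut);
  double fr = 24.0 * eps * inv6 * (2.0 * inv6 - 1.0) * inv2;
  vaxpy(F + 3 * i, fr, d);
  vaxpy(F + 3 * j, -fr, d);
}

// Ribbon twist angles of a closed chain from per-edge material normals.
// pos, m: n x 3 row-major; phi[i] = twist at vertex i (between edges i-1, i).
// Returns false if a junction is degenerate (~180 degree bend).
inline bool ribbon_twist_angles(const double *pos, const double *m, int n,
                                double *phi) {
  for (int i = 0; i < n; ++i) {
    int ip = (i + n - 1) % n;    // previous edge index
    int inext = (i + 1) % n;
    double e1[3], e2[3];
    vsub(e1, pos + 3 * i, pos + 3 * ip);
    vsub(e2, pos + 3 * inext, pos + 3 * i);
    double l1 = vnormalize(e1), l2 = vnormalize(e2);
    if (l1 <= 0 || l2 <= 0) return false;
    if (vdot(e1, e2) < -0.999999) return false;   // antiparallel tangents
    double mt[3];
    vcopy(mt, m + 3 * ip);
    transport(mt, e1, e2);       // carry previous frame across the junction
    phi[i] = signed_angle(mt, m + 3 * i, e2);
  }
  return true;
}

}  // namespace scr

#endif
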