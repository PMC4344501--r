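#include <Rcpp.h>
#include "ring.h"

using namespace Rcpp;
using namespace scr;

namespace {

// Largest probe-sphere offset s = rho + sigma/2 feasible along direction u
// (perpendicular to the local tangent) given obstacle displacements d_j,
// found by bisection on the monotone feasibility predicate
//   |s u - d_j| >= s  for all j.
double max_offset_bisect(const double *u,
                         const std::vector<std::array<double, 3>> &obs,
                         double s_min, double s_max, double tol) {
  auto feasible = [&](double s) {
    for (const auto &d : obs) {
      double dd[3] = {s * u[0] - d[0], s * u[1] - d[1], s * u[2] - d[2]};
      if (vdot(dd, dd) < s * s) return false;
    }
    return true;
  };
  if (!feasible(s_min)) return s_min;
  if (feasible(s_max)) return s_max;
  double lo = s_min, hi = s_max;
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    if (feasible(mid)) lo = mid; else hi = mid;
  }
  return lo;
}

}  // namespace

// Local intra-molecular thickness at one bead: diameter of the largest
// sphere tangent to the chain there that clears the rest of the chain (and,
// optionally, all other chains) at every azimuth around the local tangent.
// pos holds all beads of all chains (unwrapped); bead is a 0-based global
// index.  Returns 2 * min_azimuth(rho) + 1 (sigma = 1), capped at
// 2 * max_radius + 1.
// [[Rcpp::export]]
double cpp_local_thickness(NumericMatrix pos, IntegerVector chain_len,
                           LogicalVector closed, int bead,
                           int excl_halfwidth, int n_azimuth,
                           double max_radius, double tol,
                           bool include_other, double box) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);

  std::vector<int> cid(n), cpos(n), coff(chain_len.size());
  {
    int off = 0;
    for (int c = 0; c < chain_len.size(); ++c) {
      coff[c] = off;
      for (int k = 0; k < chain_len[c]; ++k) {
        cid[off + k] = c;
        cpos[off + k] = k;
      }
      off += chain_len[c];
    }
  }
  int c = cid[bead], v = cpos[bead], nc = chain_len[c];
  bool ring = closed[c];
  if (!ring && (v == 0 || v == nc - 1))
    stop("thickness probe undefined at open-chain endpoints");

  // tangent from the two flanking beads
  int vp = ring ? (v + nc - 1) % nc : v - 1;
  int vn = ring ? (v + 1) % nc : v + 1;
  double t[3];
  vsub(t, &x[3 * (coff[c] + vn)], &x[3 * (coff[c] + vp)]);
  if (vnormalize(t) < 1e-12)
    stop("undefined tangent: coincident flanking beads");

  // orthonormal basis perpendicular to t
  double e1[3] = {1, 0, 0};
  if (std::abs(t[0]) > 0.9) vset(e1, 0, 1, 0);
  double tmp = vdot(e1, t);
  vaxpy(e1, -tmp, t);
  vnormalize(e1);
  double e2[3];
  vcross(e2, t, e1);

  // obstacle set: everything except the exclusion window around the probe
  std::vector<std::array<double, 3>> obs;
  obs.reserve(n);
  for (int j = 0; j < n; ++j) {
    if (cid[j] == c) {
      int dd = std::abs(cpos[j] - v);
      if (ring) dd = std::min(dd, nc - dd);
      if (dd <= excl_halfwidth) continue;
    } else if (!include_other) {
      continue;
    }
    double d[3];
    vsub_mi(d, &x[3 * j], &x[3 * bead], box);
    obs.push_back({d[0], d[1], d[2]});
  }

  double s_min = 0.5, s_max = max_radius + 0.5;
  double rho_min = max_radius;
  for (int k = 0; k < n_azimuth; ++k) {
    double a = 2.0 * M_PI * k / n_azimuth;
    double u[3];
    for (int d = 0; d < 3; ++d)
      u[d] = std::cos(a) * e1[d] + std::sin(a) * e2[d];
    double s = max_offset_bisect(u, obs, s_min, s_max, tol);
    rho_min = std::min(rho_min, s - 0.5);
    if (rho_min <= 0) break;
  }
  return 2.0 * std::max(rho_min, 0.0) + 1.0;
}
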