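#include <Rcpp.h>
#include "forces.h"

using namespace Rcpp;
using namespace scr;

// Pairwise purely repulsive truncated LJ energy over all non-bonded pairs of
// a multi-chain system (minimum image when box > 0).  chain_len gives bead
// counts per chain; bonded neighbours (incl. ring-closure pairs) excluded.
// [[Rcpp::export]]
List cpp_energy_repulsive(NumericMatrix pos, double box,
                          IntegerVector chain_len, LogicalVector closed,
                          double eps, double rcut) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);

  // chain id + position within chain for bonded-pair exclusion
  std::vector<int> cid(n), cpos(n);
  int off = 0;
  for (int c = 0; c < chain_len.size(); ++c) {
    for (int k = 0; k < chain_len[c]; ++k) {
      cid[off + k] = c;
      cpos[off + k] = k;
    }
    off += chain_len[c];
  }

  std::vector<double> F(3 * n, 0.0);
  double U = 0.0;
  bool capped = false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (cid[i] == cid[j]) {
        int nc = chain_len[cid[i]];
        int dd = std::abs(cpos[i] - cpos[j]);
        if (dd == 1) continue;
        if (closed[cid[i]] && dd == nc - 1) continue;
      }
      capped = accum_pair_rep(x.data(), F.data(), i, j, box, eps, rcut, &U)
               || capped;
    }
  }
  return List::create(_["energy"] = U, _["capped"] = capped);
}

// Bending energy kappa * sum(1 - cos theta) of one chain.
// [[Rcpp::export]]
double cpp_energy_bend(NumericMatrix pos, bool closed, double kappa) {
  int n = pos.nrow();
  if (n < 3) stop("bending energy requires >= 3 beads");
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  // zero-length bond check: angle undefined
  int nb = closed ? n : n - 1;
  for (int i = 0; i < nb; ++i) {
    double e[3];
    vsub(e, &x[3 * ((i + 1) % n)], &x[3 * i]);
    if (vnorm(e) < 1e-12) stop("zero-length bond: bending angle undefined");
  }
  std::vector<double> F(3 * n, 0.0);
  double U = 0.0;
  int first = closed ? 0 : 1, last = closed ? n - 1 : n - 2;
  for (int i = first; i <= last; ++i)
    accum_bend(x.data(), F.data(), (i + n - 1) % n, i, (i + 1) % n, kappa, &U);
  return U;
}

// Harmonic bond energy of one chain.
// [[Rcpp::export]]
double cpp_energy_bond(NumericMatrix pos, bool closed, double k, double r0) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  std::vector<double> F(3 * n, 0.0);
  double U = 0.0;
  int nb = closed ? n : n - 1;
  for (int i = 0; i < nb; ++i)
    accum_bond(x.data(), F.data(), i, (i + 1) % n, k, r0, &U);
  return U;
}

// Ribbon twist angles (radians) of a closed ring from per-edge material
// normals; phi[i] is the twist at vertex i between edges i-1 and i.
// [[Rcpp::export]]
NumericVector cpp_twist_angles(NumericMatrix pos, NumericMatrix m) {
  int n = pos.nrow();
  if (m.nrow() != n) stop("frames must have one row per bead/edge");
  std::vector<double> x(3 * n), mm(3 * n), phi(n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      mm[3 * i + d] = m(i, d);
    }
  if (!ribbon_twist_angles(x.data(), mm.data(), n, phi.data()))
    stop("degenerate junction (~180 degree bend): twist frame undefined");
  return NumericVector(phi.begin(), phi.end());
}

// Exact closed-form writhe of a closed polygonal ring.
// [[Rcpp::export]]
double cpp_writhe(NumericMatrix pos) {
  int n = pos.nrow();
  if (n < 3) stop("writhe requires a closed ring of >= 3 beads");
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  for (int i = 0; i < n; ++i) {
    double e[3];
    vsub(e, &x[3 * ((i + 1) % n)], &x[3 * i]);
    if (vnorm(e) < 1e-12) stop("zero-length segment in ring");
  }
  return writhe_polygon(x.data(), n);
}

// One-shot force evaluation for a single chain: bonds + bending and
// optionally ribbon twist (closed rings with frames) and self-repulsion.
// Exposed for validation against finite differences and quadrature oracles.
// [[Rcpp::export]]
List cpp_chain_forces(NumericMatrix pos, Nullable<NumericMatrix> frames,
                      bool closed, double box,
                      double k_bond, double r0, double kappa,
                      double k_twist, bool torsion, bool excluded_volume,
                      double eps_rep, double rcut_rep) {
  int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  std::vector<double> F(3 * n, 0.0);
  double Ubond = 0, Ubend = 0, Utw = 0, Urep = 0;

  int nb = closed ? n : n - 1;
  for (int i = 0; i < nb; ++i)
    accum_bond(x.data(), F.data(), i, (i + 1) % n, k_bond, r0, &Ubond);
  if (n >= 3) {
    int first = closed ? 0 : 1, last = closed ? n - 1 : n - 2;
    for (int i = first; i <= last; ++i)
      accum_bend(x.data(), F.data(), (i + n - 1) % n, i, (i + 1) % n,
                 kappa, &Ubend);
  }
  std::vector<double> phi;
  if (torsion) {
    if (!closed || frames.isNull())
      stop("torsion requires a closed ring with material frames");
    NumericMatrix mR(frames);
    std::vector<double> mm(3 * n);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) mm[3 * i + d] = mR(i, d);
    phi.resize(n);
    if (!ribbon_twist_angles(x.data(), mm.data(), n, phi.data()))
      stop("degenerate junction: twist frame undefined");
    for (int i = 0; i < n; ++i)
      accum_twist_force(x.data(), F.data(), (i + n - 1) % n, i, (i + 1) % n,
                        k_twist, phi[i], &Utw);
  }
  if (excluded_volume) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int dd = std::abs(i - j);
        if (dd == 1 || (closed && dd == n - 1)) continue;
        accum_pair_rep(x.data(), F.data(), i, j, box, eps_rep, rcut_rep,
                       &Urep);
      }
  }
  NumericMatrix Fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Fout(i, d) = F[3 * i + d];
  return List::create(_["forces"] = Fout,
                      _["bond"] = Ubond, _["bend"] = Ubend,
                      _["twist"] = Utw, _["repulsion"] = Urep,
                      _["phi"] = NumericVector(phi.begin(), phi.end()));
}
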