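#include <Rcpp.h>
#include "forces.h"
#include "rng.h"

using namespace Rcpp;
using namespace scr;

// Metropolis Monte Carlo sampler of the same Hamiltonian as the Brownian
// dynamics engine (harmonic bonds, kappa(1 - cos) bending, truncated
// repulsive LJ, optional enhancer-promoter well).  For torsionally
// constrained rings the twist energy is evaluated in the homogeneous-twist
// approximation E = 2 pi^2 k_twist (DeltaLk - Wr)^2 / N, with the writhe
// tracked incrementally move by move.
//
// Moves: capped-amplitude crankshaft rotations of sub-arcs, single-bead
// displacements, and (for multi-chain systems) whole-chain translations.
// The displacement cap (max_disp) keeps chain crossings impossible as long
// as it stays below the ~1.6 sigma jump the excluded volume would require,
// so ring topology is preserved.

namespace {

struct Chain {
  int off, n;
  bool closed;
};

// Cell grid for excluded-volume queries.  Periodic boxes wrap the cell
// indices; open (dilute) systems use a grid over the bounding box of the
// coordinates, rebuilt when a bead wanders outside.
struct Grid {
  bool active = false, periodic = false, need_rebuild = false;
  double box = 0, cell = 1.0;
  double lo[3] = {0, 0, 0};
  int nc[3] = {0, 0, 0};
  std::vector<std::vector<int>> cells;
  std::vector<int> where;

  inline void cell_of(const double *p, int *a) const {
    for (int d = 0; d < 3; ++d) {
      int c;
      if (periodic) {
        double w = p[d] - box * std::floor(p[d] / box);
        c = (int)(w / cell);
        if (c >= nc[d]) c = nc[d] - 1;
      } else {
        c = (int)std::floor((p[d] - lo[d]) / cell);
        if (c < 0) c = 0;
        if (c >= nc[d]) c = nc[d] - 1;
      }
      a[d] = c;
    }
  }
  int index(const double *p) const {
    int a[3];
    cell_of(p, a);
    return (a[0] * nc[1] + a[1]) * nc[2] + a[2];
  }
  void build(const std::vector<double> &x, int n, double box_, double rcut) {
    box = box_;
    periodic = box > 0;
    need_rebuild = false;
    if (periodic) {
      int k = (int)std::floor(box / rcut);
      active = k >= 3;
      if (!active) return;
      if (k > 200) k = 200;
      nc[0] = nc[1] = nc[2] = k;
      cell = box / k;
    } else {
      active = n > 0;
      if (!active) return;
      cell = rcut;
      double hi[3];
      for (int d = 0; d < 3; ++d) { lo[d] = x[d]; hi[d] = x[d]; }
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          lo[d] = std::min(lo[d], x[3 * i + d]);
          hi[d] = std::max(hi[d], x[3 * i + d]);
        }
      for (int d = 0; d < 3; ++d) {
        lo[d] -= 6.0 * cell;       // slack so beads can wander before rebuild
        nc[d] = (int)std::ceil((hi[d] + 6.0 * cell - lo[d]) / cell) + 1;
      }
      double ntot = (double)nc[0] * nc[1] * nc[2];
      if (ntot > 4e6) {            // coarsen rather than blow up memory
        double f = std::cbrt(ntot / 4e6);
        cell *= f;
        for (int d = 0; d < 3; ++d)
          nc[d] = (int)std::ceil((hi[d] + 6.0 - lo[d]) / cell) + 1;
      }
    }
    cells.assign((size_t)nc[0] * nc[1] * nc[2], {});
    where.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int idx = index(&x[3 * i]);
      cells[idx].push_back(i);
      where[i] = idx;
    }
  }
  void update(int i, const double *p) {
    if (!active) return;
    if (!periodic)
      for (int d = 0; d < 3; ++d)
        if (p[d] < lo[d] + cell || p[d] > lo[d] + (nc[d] - 1) * cell)
          need_rebuild = true;     // near the rim: rebuild after this move
    int idx = index(p);
    if (idx == where[i]) return;
    auto &old = cells[where[i]];
    old.erase(std::find(old.begin(), old.end(), i));
    cells[idx].push_back(i);
    where[i] = idx;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos, IntegerVector chain_len,
                LogicalVector closed, double box,
                double eps_rep, double rcut_rep, double k_bond, double r0,
                double kappa, bool excluded_volume,
                bool twist_mode, double k_twist, NumericVector delta_lk,
                IntegerMatrix ep_pairs, double ep_eps, double ep_rcut,
                int n_sweeps, int sample_every,
                double max_disp, double local_disp, int max_arc,
                double p_local, double p_trans) {
  int n = pos.nrow();
  int nchain = chain_len.size();
  FastRng rng;
  rng.seed_from_r();
  std::vector<Chain> chains(nchain);
  std::vector<int> cid(n), cpos(n);
  {
    int off = 0;
    for (int c = 0; c < nchain; ++c) {
      chains[c] = {off, chain_len[c], (bool)closed[c]};
      for (int k = 0; k < chain_len[c]; ++k) {
        cid[off + k] = c;
        cpos[off + k] = k;
      }
      off += chain_len[c];
    }
    if (off != n) stop("chain_len does not sum to bead count");
  }
  if (twist_mode)
    for (int c = 0; c < nchain; ++c)
      if (!chains[c].closed) stop("twist_mode requires closed rings");

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);

  Grid grid;
  if (excluded_volume) grid.build(x, n, box, std::max(rcut_rep, 1.0));

  auto bonded = [&](int i, int j) {
    if (cid[i] != cid[j]) return false;
    const Chain &c = chains[cid[i]];
    int dd = std::abs(cpos[i] - cpos[j]);
    return dd == 1 || (c.closed && dd == c.n - 1);
  };

  std::vector<int> stamp(n, -1);
  int stamp_now = 0;

  // repulsive energy of bead b placed at p against all unstamped beads
  auto rep_energy_at = [&](int b, const double *p) {
    double U = 0;
    auto pair_u = [&](int j) {
      if (j == b || stamp[j] == stamp_now || bonded(b, j)) return;
      double d[3];
      vsub_mi(d, p, &x[3 * j], box);
      double r2 = vdot(d, d);
      if (r2 >= rcut_rep * rcut_rep) return;
      if (r2 < 1e-4) r2 = 1e-4;
      double inv6 = 1.0 / (r2 * r2 * r2);
      U += 4.0 * eps_rep * inv6 * (inv6 - 1.0);
    };
    if (grid.active) {
      int a[3];
      grid.cell_of(p, a);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int ix = a[0] + dx, iy = a[1] + dy, iz = a[2] + dz;
            if (grid.periodic) {
              ix = (ix + grid.nc[0]) % grid.nc[0];
              iy = (iy + grid.nc[1]) % grid.nc[1];
              iz = (iz + grid.nc[2]) % grid.nc[2];
            } else if (ix < 0 || iy < 0 || iz < 0 || ix >= grid.nc[0] ||
                       iy >= grid.nc[1] || iz >= grid.nc[2]) {
              continue;
            }
            for (int j : grid.cells[((size_t)ix * grid.nc[1] + iy) *
                                    grid.nc[2] + iz])
              pair_u(j);
          }
    } else {
      for (int j = 0; j < n; ++j) pair_u(j);
    }
    return U;
  };

  auto bend_at = [&](int c, int v) {  // vertex v (chain-local) bending energy
    const Chain &ch = chains[c];
    if (!ch.closed && (v <= 0 || v >= ch.n - 1)) return 0.0;
    int a = ch.off + (v + ch.n - 1) % ch.n;
    int b = ch.off + v;
    int cc = ch.off + (v + 1) % ch.n;
    double e1[3], e2[3];
    vsub(e1, &x[3 * b], &x[3 * a]);
    vsub(e2, &x[3 * cc], &x[3 * b]);
    double l1 = vnorm(e1), l2 = vnorm(e2);
    if (l1 <= 0 || l2 <= 0) return 0.0;
    return kappa * (1.0 - vdot(e1, e2) / (l1 * l2));
  };
  auto bond_u = [&](int i, int j) {
    double e[3];
    vsub(e, &x[3 * j], &x[3 * i]);
    double d = vnorm(e) - r0;
    return 0.5 * k_bond * d * d;
  };
  int n_ep = ep_pairs.nrow();
  double epsh = ep_shift(ep_eps, ep_rcut);
  auto ep_u = [&](int e) {
    double d[3];
    vsub_mi(d, &x[3 * ep_pairs(e, 0)], &x[3 * ep_pairs(e, 1)], box);
    double r2 = vdot(d, d);
    if (r2 >= ep_rcut * ep_rcut) return 0.0;
    if (r2 < 1e-4) r2 = 1e-4;
    double inv6 = 1.0 / (r2 * r2 * r2);
    return 4.0 * ep_eps * inv6 * (inv6 - 1.0) - epsh;
  };

  // incremental writhe: sum of pair terms between changed edges (chain-local
  // tail-vertex indices in `edges`) and all static edges of the same ring
  auto wr_partial = [&](int c, const std::vector<int> &edges,
                        const std::vector<char> &is_changed) {
    const Chain &ch = chains[c];
    double s = 0;
    for (int e : edges) {
      int e2 = (e + 1) % ch.n;
      for (int f = 0; f < ch.n; ++f) {
        if (is_changed[f]) continue;
        int df = std::abs(e - f);
        if (df <= 1 || df == ch.n - 1) continue;  // same or adjacent edge
        int f2 = (f + 1) % ch.n;
        s += writhe_pair(&x[3 * (ch.off + e)], &x[3 * (ch.off + e2)],
                         &x[3 * (ch.off + f)], &x[3 * (ch.off + f2)]);
      }
    }
    return 2.0 * s;
  };

  std::vector<double> wr(nchain, 0.0);
  if (twist_mode)
    for (int c = 0; c < nchain; ++c)
      wr[c] = writhe_polygon(&x[3 * chains[c].off], chains[c].n);
  auto twist_u = [&](int c, double w) {
    if (!twist_mode) return 0.0;
    double d = delta_lk[c] - w;
    return 2.0 * M_PI * M_PI * k_twist * d * d / chains[c].n;
  };

  int n_samples = sample_every > 0 ? n_sweeps / sample_every : 0;
  List samp_pos(n_samples);
  NumericMatrix samp_wr(n_samples, nchain);
  NumericMatrix samp_bend(n_samples, nchain);
  int isamp = 0;
  long acc[3] = {0, 0, 0}, att[3] = {0, 0, 0};

  std::vector<int> moved;
  std::vector<double> xold;
  std::vector<char> is_changed;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      int b = (int)(rng.unif() * n);
      if (b >= n) b = n - 1;
      int c = cid[b];
      const Chain &ch = chains[c];
      double u = rng.unif();
      int type;  // 0 local, 1 crank, 2 translate
      if (u < p_local || ch.n < 4)
        type = 0;
      else if (nchain > 1 && u < p_local + p_trans)
        type = 2;
      else
        type = 1;
      ++att[type];
      ++stamp_now;
      moved.clear();
      double dE = 0, dwr = 0;

      if (type == 0) {
        int v = cpos[b];
        double pnew[3];
        for (int d = 0; d < 3; ++d)
          pnew[d] = x[3 * b + d] + local_disp * (2.0 * rng.unif() - 1.0);
        stamp[b] = stamp_now;
        // old local energy
        double e_old = 0, e_new = 0;
        if (excluded_volume) e_old += rep_energy_at(b, &x[3 * b]);
        for (int dv = -1; dv <= 1; ++dv) e_old += bend_at(c, (v + dv + ch.n) % ch.n);
        int vprev = ch.off + (v + ch.n - 1) % ch.n;
        int vnext = ch.off + (v + 1) % ch.n;
        bool has_prev = ch.closed || v > 0;
        bool has_next = ch.closed || v < ch.n - 1;
        if (has_prev) e_old += bond_u(vprev, b);
        if (has_next) e_old += bond_u(b, vnext);
        for (int e = 0; e < n_ep; ++e)
          if (ep_pairs(e, 0) == b || ep_pairs(e, 1) == b) e_old += ep_u(e);
        std::vector<int> chedges;
        if (twist_mode) {
          is_changed.assign(ch.n, 0);
          if (has_prev) { chedges.push_back((v + ch.n - 1) % ch.n); }
          if (has_next) { chedges.push_back(v); }
          for (int e : chedges) is_changed[e] = 1;
          dwr -= wr_partial(c, chedges, is_changed);
          e_old += twist_u(c, wr[c]);
        }
        double save[3];
        vcopy(save, &x[3 * b]);
        vcopy(&x[3 * b], pnew);
        if (excluded_volume) e_new += rep_energy_at(b, &x[3 * b]);
        for (int dv = -1; dv <= 1; ++dv) e_new += bend_at(c, (v + dv + ch.n) % ch.n);
        if (has_prev) e_new += bond_u(vprev, b);
        if (has_next) e_new += bond_u(b, vnext);
        for (int e = 0; e < n_ep; ++e)
          if (ep_pairs(e, 0) == b || ep_pairs(e, 1) == b) e_new += ep_u(e);
        if (twist_mode) {
          dwr += wr_partial(c, chedges, is_changed);
          e_new += twist_u(c, wr[c] + dwr);
        }
        dE = e_new - e_old;
        if (dE < 700 && rng.unif() < std::exp(-dE)) {
          ++acc[0];
          if (excluded_volume) grid.update(b, &x[3 * b]);
          wr[c] += dwr;
        } else {
          vcopy(&x[3 * b], save);
        }
      } else if (type == 1) {
        // crankshaft about the chord through vertices i and j
        int len = 2 + (int)(rng.unif() * (std::min(max_arc, ch.n - 2) - 1));
        int vi = cpos[b];
        int vj = vi + len;
        if (!ch.closed && vj >= ch.n) { continue; }
        int gi = ch.off + vi, gj = ch.off + (vj % ch.n);
        double axis[3];
        vsub(axis, &x[3 * gj], &x[3 * gi]);
        if (vnormalize(axis) < 1e-9) continue;
        // moved beads: vi+1 .. vj-1 (chain-local, cyclic)
        moved.clear();
        double rho_max = 0;
        for (int v = vi + 1; v < vj; ++v) {
          int g = ch.off + (v % ch.n);
          moved.push_back(g);
          double d[3], ax[3];
          vsub(d, &x[3 * g], &x[3 * gi]);
          vcross(ax, axis, d);
          rho_max = std::max(rho_max, vnorm(ax));
        }
        double thcap = rho_max > 1e-9 ? std::min(M_PI, max_disp / rho_max)
                                      : M_PI;
        double theta = thcap * (2.0 * rng.unif() - 1.0);
        for (int g : moved) stamp[g] = stamp_now;

        double e_old = bend_at(c, vi) + bend_at(c, vj % ch.n);
        if (excluded_volume)
          for (int g : moved) e_old += rep_energy_at(g, &x[3 * g]);
        for (int e = 0; e < n_ep; ++e)
          if (stamp[ep_pairs(e, 0)] == stamp_now ||
              stamp[ep_pairs(e, 1)] == stamp_now)
            e_old += ep_u(e);
        std::vector<int> chedges;
        if (twist_mode) {
          is_changed.assign(ch.n, 0);
          for (int v = vi; v < vj; ++v) {
            chedges.push_back(v % ch.n);
            is_changed[v % ch.n] = 1;
          }
          dwr -= wr_partial(c, chedges, is_changed);
          e_old += twist_u(c, wr[c]);
        }
        xold.clear();
        for (int g : moved)
          for (int d = 0; d < 3; ++d) xold.push_back(x[3 * g + d]);
        for (int g : moved) {
          double d[3];
          vsub(d, &x[3 * g], &x[3 * gi]);
          vrotate(d, axis, theta);
          vadd(&x[3 * g], d, &x[3 * gi]);
        }
        double e_new = bend_at(c, vi) + bend_at(c, vj % ch.n);
        if (excluded_volume)
          for (int g : moved) e_new += rep_energy_at(g, &x[3 * g]);
        for (int e = 0; e < n_ep; ++e)
          if (stamp[ep_pairs(e, 0)] == stamp_now ||
              stamp[ep_pairs(e, 1)] == stamp_now)
            e_new += ep_u(e);
        if (twist_mode) {
          dwr += wr_partial(c, chedges, is_changed);
          e_new += twist_u(c, wr[c] + dwr);
        }
        dE = e_new - e_old;
        if (dE < 700 && rng.unif() < std::exp(-dE)) {
          ++acc[1];
          if (excluded_volume)
            for (int g : moved) grid.update(g, &x[3 * g]);
          wr[c] += dwr;
        } else {
          for (size_t k = 0; k < moved.size(); ++k)
            for (int d = 0; d < 3; ++d) x[3 * moved[k] + d] = xold[3 * k + d];
        }
      } else {
        // whole-chain translation (inter-chain repulsion only)
        double shift[3];
        for (int d = 0; d < 3; ++d) shift[d] = max_disp * (2.0 * rng.unif() - 1.0);
        moved.clear();
        for (int k = 0; k < ch.n; ++k) {
          moved.push_back(ch.off + k);
          stamp[ch.off + k] = stamp_now;
        }
        double e_old = 0, e_new = 0;
        if (excluded_volume)
          for (int g : moved) e_old += rep_energy_at(g, &x[3 * g]);
        for (int g : moved) vaxpy(&x[3 * g], 1.0, shift);
        if (excluded_volume)
          for (int g : moved) e_new += rep_energy_at(g, &x[3 * g]);
        dE = e_new - e_old;
        if (dE < 700 && rng.unif() < std::exp(-dE)) {
          ++acc[2];
          if (excluded_volume)
            for (int g : moved) grid.update(g, &x[3 * g]);
        } else {
          for (int g : moved) vaxpy(&x[3 * g], -1.0, shift);
        }
      }
    }

    if (excluded_volume && grid.need_rebuild)
      grid.build(x, n, box, std::max(rcut_rep, 1.0));

    if (twist_mode && sweep % 100 == 0)  // kill incremental-writhe drift
      for (int c = 0; c < nchain; ++c)
        wr[c] = writhe_polygon(&x[3 * chains[c].off], chains[c].n);

    if (sample_every > 0 && sweep % sample_every == 0) {
      NumericMatrix sp(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) sp(i, d) = x[3 * i + d];
      samp_pos[isamp] = sp;
      for (int c = 0; c < nchain; ++c) {
        const Chain &ch = chains[c];
        samp_wr(isamp, c) =
            twist_mode ? writhe_polygon(&x[3 * ch.off], ch.n) : NA_REAL;
        double ub = 0;
        int first = ch.closed ? 0 : 1, last = ch.closed ? ch.n - 1 : ch.n - 2;
        for (int v = first; v <= last; ++v) ub += bend_at(c, v);
        samp_bend(isamp, c) = ub;
      }
      ++isamp;
    }
    if (sweep % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos_out(i, d) = x[3 * i + d];
  return List::create(
      _["pos"] = pos_out, _["samples"] = samp_pos, _["wr"] = samp_wr,
      _["bend_energy"] = samp_bend,
      _["acc"] = NumericVector::create(
          att[0] ? (double)acc[0] / att[0] : NA_REAL,
          att[1] ? (double)acc[1] / att[1] : NA_REAL,
          att[2] ? (double)acc[2] / att[2] : NA_REAL));
}
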