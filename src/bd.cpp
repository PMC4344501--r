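#include <Rcpp.h>
#include "forces.h"
#include "rng.h"

using namespace Rcpp;
using namespace scr;

namespace {

struct Chain {
  int off, n;
  bool closed, torsion;
};

// Verlet neighbour list for the short-range repulsion, built either through
// a cell grid (PBC, box large enough) or a direct O(N^2) sweep.
struct NeighbourList {
  double rlist = 0, skin = 0;
  std::vector<std::pair<int, int>> pairs;
  std::vector<double> x_build;

  static bool bonded(const std::vector<int> &cid, const std::vector<int> &cpos,
                     const std::vector<Chain> &chains, int i, int j) {
    if (cid[i] != cid[j]) return false;
    const Chain &c = chains[cid[i]];
    int dd = std::abs(cpos[i] - cpos[j]);
    return dd == 1 || (c.closed && dd == c.n - 1);
  }

  void build(const std::vector<double> &x, int n, double box,
             const std::vector<int> &cid, const std::vector<int> &cpos,
             const std::vector<Chain> &chains) {
    pairs.clear();
    x_build = x;
    int ncell = box > 0 ? (int)std::floor(box / rlist) : 0;
    if (box > 0 && ncell >= 3) {
      // array cell grid on wrapped coordinates
      double cell = box / ncell;
      int ntot = ncell * ncell * ncell;
      std::vector<int> head(ntot, -1), nxt(n, -1), ci(n), cj(n), ck(n);
      for (int i = 0; i < n; ++i) {
        int a[3];
        for (int d = 0; d < 3; ++d) {
          double w = x[3 * i + d] - box * std::floor(x[3 * i + d] / box);
          int c = (int)(w / cell);
          if (c >= ncell) c = ncell - 1;
          a[d] = c;
        }
        ci[i] = a[0]; cj[i] = a[1]; ck[i] = a[2];
        int idx = (a[0] * ncell + a[1]) * ncell + a[2];
        nxt[i] = head[idx];
        head[idx] = i;
      }
      for (int i = 0; i < n; ++i) {
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int ax = (ci[i] + dx + ncell) % ncell;
              int ay = (cj[i] + dy + ncell) % ncell;
              int az = (ck[i] + dz + ncell) % ncell;
              int idx = (ax * ncell + ay) * ncell + az;
              for (int j = head[idx]; j != -1; j = nxt[j]) {
                if (j <= i) continue;
                double d[3];
                vsub_mi(d, &x[3 * i], &x[3 * j], box);
                if (vdot(d, d) < rlist * rlist &&
                    !bonded(cid, cpos, chains, i, j))
                  pairs.emplace_back(i, j);
              }
            }
      }
      // cell grid can visit a pair twice when ncell == 3; dedupe
      if (ncell == 3) {
        std::sort(pairs.begin(), pairs.end());
        pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double d[3];
          vsub_mi(d, &x[3 * i], &x[3 * j], box);
          if (vdot(d, d) < rlist * rlist && !bonded(cid, cpos, chains, i, j))
            pairs.emplace_back(i, j);
        }
    }
  }

  bool stale(const std::vector<double> &x, int n) const {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = x[i] - x_build[i], dy = x[i + 1] - x_build[i + 1],
             dz = x[i + 2] - x_build[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

}  // namespace

// Overdamped (Euler-Maruyama) Brownian dynamics of a multi-chain system at
// kT = 1.  Coordinates are propagated unwrapped; periodicity enters only
// through minimum-image distances in the non-bonded terms.  Closed chains
// with torsion = TRUE carry per-edge material normals evolved by parallel
// transport plus rotational Langevin dynamics about the local tangent.
// [[Rcpp::export]]
List cpp_bd_run(NumericMatrix pos, IntegerVector chain_len,
                LogicalVector closed, LogicalVector torsion,
                Nullable<NumericMatrix> frames_in, double box,
                double eps_rep, double rcut_rep, double k_bond, double r0,
                double kappa, double k_twist,
                IntegerMatrix ep_pairs, double ep_eps, double ep_rcut,
                bool excluded_volume,
                double dt, double gamma, double gamma_t,
                int n_steps, int sample_every) {
  int n = pos.nrow();
  int nchain = chain_len.size();
  FastRng rng;
  rng.seed_from_r();
  std::vector<Chain> chains(nchain);
  std::vector<int> cid(n), cpos(n);
  {
    int off = 0;
    for (int c = 0; c < nchain; ++c) {
      chains[c] = {off, chain_len[c], (bool)closed[c], (bool)torsion[c]};
      if (chains[c].torsion && !chains[c].closed)
        stop("torsion requires closed rings");
      for (int k = 0; k < chain_len[c]; ++k) {
        cid[off + k] = c;
        cpos[off + k] = k;
      }
      off += chain_len[c];
    }
    if (off != n) stop("chain_len does not sum to bead count");
  }

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);

  bool any_torsion = false;
  for (int c = 0; c < nchain; ++c) any_torsion |= chains[c].torsion;
  std::vector<double> m;
  if (any_torsion) {
    if (frames_in.isNull()) stop("torsion chains require material frames");
    NumericMatrix mR(frames_in);
    if (mR.nrow() != n) stop("frames must have one row per bead");
    m.resize(3 * n);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) m[3 * i + d] = mR(i, d);
  }

  NeighbourList nl;
  nl.skin = 0.5;
  nl.rlist = rcut_rep + nl.skin;
  if (excluded_volume) nl.build(x, n, box, cid, cpos, chains);

  int n_ep = ep_pairs.nrow();
  std::vector<double> F(3 * n), phi(n, 0.0), unew(3 * n), uold(3 * n);
  double sq_noise = std::sqrt(2.0 * dt / gamma);
  double sq_noise_t = std::sqrt(2.0 * dt / gamma_t);

  // twist angles are cached across steps (exact incremental update after
  // the frame rotations) and re-synchronised from the frames at sampling
  if (any_torsion) {
    for (int c = 0; c < nchain; ++c) {
      const Chain &ch = chains[c];
      if (!ch.torsion) continue;
      if (!ribbon_twist_angles(&x[3 * ch.off], &m[3 * ch.off], ch.n,
                               &phi[ch.off]))
        stop("degenerate junction in initial conformation");
    }
  }
  std::vector<double> dpsi(n, 0.0);

  int n_samples = sample_every > 0 ? n_steps / sample_every : 0;
  List samp_pos(n_samples), samp_phi(n_samples);
  NumericMatrix samp_rg(n_samples, nchain);
  NumericMatrix samp_en(n_samples, 5);
  colnames(samp_en) =
      CharacterVector::create("bond", "bend", "twist", "repulsion", "ep");
  bool capped_any = false;
  int isamp = 0;

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(F.begin(), F.end(), 0.0);
    double Ubond = 0, Ubend = 0, Utw = 0, Urep = 0, Uep = 0;

    for (int c = 0; c < nchain; ++c) {
      const Chain &ch = chains[c];
      int nn = ch.n, o = ch.off;
      int nb = ch.closed ? nn : nn - 1;
      for (int i = 0; i < nb; ++i)
        accum_bond(x.data(), F.data(), o + i, o + (i + 1) % nn, k_bond, r0,
                   &Ubond);
      if (nn >= 3) {
        int first = ch.closed ? 0 : 1, last = ch.closed ? nn - 1 : nn - 2;
        for (int i = first; i <= last; ++i)
          accum_bend(x.data(), F.data(), o + (i + nn - 1) % nn, o + i,
                     o + (i + 1) % nn, kappa, &Ubend);
      }
      if (ch.torsion) {
        for (int i = 0; i < nn; ++i)   // phi cached from previous step
          accum_twist_force(x.data(), F.data(), o + (i + nn - 1) % nn, o + i,
                            o + (i + 1) % nn, k_twist, phi[o + i], &Utw);
      }
    }

    if (excluded_volume) {
      if (nl.stale(x, n)) nl.build(x, n, box, cid, cpos, chains);
      for (auto &pr : nl.pairs)
        capped_any = accum_pair_rep(x.data(), F.data(), pr.first, pr.second,
                                    box, eps_rep, rcut_rep, &Urep) ||
                     capped_any;
    }
    for (int e = 0; e < n_ep; ++e)
      accum_pair_ep(x.data(), F.data(), ep_pairs(e, 0), ep_pairs(e, 1), box,
                    ep_eps, ep_rcut, &Uep);

    // store old tangents of torsion chains before moving beads
    if (any_torsion) {
      for (int c = 0; c < nchain; ++c) {
        const Chain &ch = chains[c];
        if (!ch.torsion) continue;
        for (int i = 0; i < ch.n; ++i) {
          int a = ch.off + i, b = ch.off + (i + 1) % ch.n;
          double e[3];
          vsub(e, &x[3 * b], &x[3 * a]);
          vnormalize(e);
          vcopy(&uold[3 * a], e);
        }
      }
    }

    double max_disp2 = 0;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx0 = dt / gamma * F[i] + sq_noise * rng.norm();
      double dx1 = dt / gamma * F[i + 1] + sq_noise * rng.norm();
      double dx2 = dt / gamma * F[i + 2] + sq_noise * rng.norm();
      x[i] += dx0; x[i + 1] += dx1; x[i + 2] += dx2;
      double d2 = dx0 * dx0 + dx1 * dx1 + dx2 * dx2;
      if (d2 > max_disp2) max_disp2 = d2;
    }
    if (max_disp2 > 0.25)
      stop("BD instability: displacement > 0.5 sigma in one step (step %d)",
           step);

    if (any_torsion) {
      for (int c = 0; c < nchain; ++c) {
        const Chain &ch = chains[c];
        if (!ch.torsion) continue;
        int nn = ch.n, o = ch.off;
        // parallel-transport each edge frame to the new tangent
        for (int i = 0; i < nn; ++i) {
          int a = o + i, b = o + (i + 1) % nn;
          double e[3];
          vsub(e, &x[3 * b], &x[3 * a]);
          vnormalize(e);
          vcopy(&unew[3 * a], e);
          transport(&m[3 * a], &uold[3 * a], &unew[3 * a]);
          // re-orthonormalize against numerical drift
          double *mi = &m[3 * a];
          vaxpy(mi, -vdot(mi, e), e);
          vnormalize(mi);
        }
        // torsional relaxation: rotational Langevin step about the tangent
        if (!ribbon_twist_angles(&x[3 * o], &m[3 * o], nn, &phi[o]))
          stop("degenerate junction during BD (180 degree bend)");
        for (int i = 0; i < nn; ++i) {
          double tau = -k_twist * (phi[o + i] - phi[o + (i + 1) % nn]);
          dpsi[o + i] = dt / gamma_t * tau + sq_noise_t * rng.norm();
        }
        for (int i = 0; i < nn; ++i) {
          vrotate(&m[3 * (o + i)], &unew[3 * (o + i)], dpsi[o + i]);
          // exact incremental update of the cached junction angles
          phi[o + i] += dpsi[o + i];
          phi[o + (i + 1) % nn] -= dpsi[o + i];
        }
      }
    }

    if (sample_every > 0 && step % sample_every == 0) {
      NumericMatrix sp(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) sp(i, d) = x[3 * i + d];
      samp_pos[isamp] = sp;
      if (any_torsion) {
        for (int c = 0; c < nchain; ++c) {
          const Chain &ch = chains[c];
          if (ch.torsion)
            ribbon_twist_angles(&x[3 * ch.off], &m[3 * ch.off], ch.n,
                                &phi[ch.off]);
        }
        samp_phi[isamp] = NumericVector(phi.begin(), phi.end());
      }
      for (int c = 0; c < nchain; ++c) {
        const Chain &ch = chains[c];
        double com[3] = {0, 0, 0};
        for (int i = 0; i < ch.n; ++i) vadd(com, com, &x[3 * (ch.off + i)]);
        vscale(com, 1.0 / ch.n);
        double rg2 = 0;
        for (int i = 0; i < ch.n; ++i) {
          double d[3];
          vsub(d, &x[3 * (ch.off + i)], com);
          rg2 += vdot(d, d);
        }
        samp_rg(isamp, c) = std::sqrt(rg2 / ch.n);
      }
      samp_en(isamp, 0) = Ubond; samp_en(isamp, 1) = Ubend;
      samp_en(isamp, 2) = Utw;   samp_en(isamp, 3) = Urep;
      samp_en(isamp, 4) = Uep;
      ++isamp;
    }
    if (step % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos_out(i, d) = x[3 * i + d];
  NumericMatrix m_out(any_torsion ? n : 0, 3);
  if (any_torsion)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) m_out(i, d) = m[3 * i + d];

  return List::create(
      _["pos"] = pos_out, _["frames"] = m_out,
      _["samples"] = samp_pos, _["sample_twist"] = samp_phi,
      _["rg"] = samp_rg, _["energy"] = samp_en, _["capped"] = capped_any);
}
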