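#' Metropolis Monte Carlo sampling of the ring Hamiltonian
#'
#' Equilibrium sampler of the same energy function as the Brownian
#' dynamics engine: harmonic bonds, `kappa (1 - cos theta)` bending,
#' truncated-LJ excluded volume and the optional enhancer-promoter well.
#' Moves are capped-amplitude crankshaft rotations of random sub-arcs,
#' single-bead displacements, and whole-molecule translations in periodic
#' systems.  The excluded volume keeps non-bonded beads about 0.8 sigma
#' apart, so hopping to the far side of another strand would require a
#' jump of at least ~1.6 sigma; displacement caps below ~1.5 sigma
#' therefore preserve ring topology (knotting, catenation) between
#' accepted states.
#'
#' For torsionally constrained rings (`delta_lk` not `NA`), the twist
#' degrees of freedom are integrated out in the homogeneous-twist
#' approximation: twist relaxes much faster than the backbone, so the
#' twist free energy is \eqn{2\pi^2 k_t (\Delta Lk - Wr)^2 / N} and the
#' writhe is tracked incrementally move by move (refreshed exactly at
#' intervals).
#'
#' The sampler serves two roles: an independent cross-check of the
#' Brownian dynamics ensembles, and a cheap route to long-timescale
#' ensemble averages (global shape, contact statistics) that BD reaches
#' only slowly.
#'
#' @param state a [system_state()].
#' @param ff a [force_field()].
#' @param n_sweeps number of sweeps (one attempted move per bead each).
#' @param sample_every store a frame every this many sweeps.
#' @param delta_lk per-molecule linking deficit (`NA` = torsionally
#'   unconstrained; recycled across molecules).
#' @param ep optional [ep_spec()] applied within every molecule.
#' @param excluded_volume toggle the excluded-volume term.
#' @param max_disp displacement cap per crankshaft/translation move
#'   (sigma_LJ).  Crossing another strand would need a jump of about
#'   1.6 sigma given the excluded volume, so caps below ~1.5 preserve
#'   topology.
#' @param local_disp amplitude of single-bead displacement moves; small
#'   because it works against the stiff bonds (default 0.06 sigma, about
#'   twice the equilibrium bond-length fluctuation).
#' @param max_arc largest crankshaft arc length (beads).
#' @param p_local,p_trans move-mix probabilities (the remainder are
#'   crankshaft moves).
#' @param seed RNG seed (`NA` to continue the ambient stream).
#' @return An `sc_trajectory` (with `$wr` per-frame writhe for constrained
#'   rings, `$acc` acceptance rates and `$final_state` attached).
#' @export
mc_sample <- function(state, ff = force_field(), n_sweeps = 1000,
                      sample_every = 10, delta_lk = NA, ep = NULL,
                      excluded_volume = TRUE, max_disp = 1.2,
                      local_disp = 0.06, max_arc = NULL,
                      p_local = 0.2, p_trans = 0.1, seed = NA) {
  stopifnot(inherits(state, "system_state"))
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  confs <- unwrap_to_confs(state)
  sys <- as_chain_set(confs)
  L <- state$box_length
  nring <- length(sys$len)
  dlk <- rep_len(delta_lk, nring)
  twist_mode <- any(!is.na(dlk))
  if (twist_mode && any(is.na(dlk)))
    stop("mixing constrained and nicked molecules in one MC run is not supported")
  if (is.null(max_arc)) max_arc <- max(4L, floor(max(sys$len) / 2))
  ep_pairs <- matrix(integer(), 0, 2)
  if (!is.null(ep)) {
    off <- c(0L, cumsum(sys$len))
    ok <- sys$len >= pmax(ep$enhancer_bead, ep$promoter_bead)
    ep_pairs <- cbind(off[which(ok)] + ep$enhancer_bead - 1L,
                      off[which(ok)] + ep$promoter_bead - 1L)
  }
  res <- cpp_mc_run(sys$pos, sys$len, sys$closed,
                    if (is.finite(L)) L else -1,
                    ff$eps_rep, ff$r_cut_rep, ff$k_bond, ff$r0_bond,
                    ff$eps_bend, excluded_volume,
                    twist_mode, ff$k_twist,
                    ifelse(is.na(dlk), 0, dlk),
                    ep_pairs, if (is.null(ep)) 0 else ep$eps,
                    if (is.null(ep)) 2 else ep$rcut,
                    as.integer(n_sweeps), as.integer(sample_every),
                    max_disp, local_disp, as.integer(max_arc),
                    p_local, p_trans)
  nf <- length(res$samples)
  traj <- sc_trajectory(res$samples, twist = NULL, ring_len = sys$len,
                        closed = sys$closed,
                        torsion = rep(twist_mode, nring), box = L,
                        steps = seq_len(nf) * sample_every,
                        rg = NULL, energy = NULL,
                        metadata = list(ff = ff, sampler = "mc",
                                        delta_lk = dlk, ep = ep))
  traj$wr <- res$wr
  traj$bend_energy <- res$bend_energy
  traj$acc <- res$acc
  pos_list <- local({
    off <- c(0L, cumsum(sys$len))
    lapply(seq_len(nring), function(r)
      res$pos[(off[r] + 1):off[r + 1], , drop = FALSE])
  })
  wrapped <- wrap_coordinates(pos_list, L)
  rings <- lapply(seq_len(nring), function(r) {
    conf <- state$rings[[r]]
    conf$pos <- wrapped$pos[[r]]
    conf
  })
  traj$final_state <- system_state(rings, L, wrapped$flags,
                                   step = state$step)
  traj
}
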