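#' Reduced simulation units
#'
#' Conversion constants between reduced (Lennard-Jones) units and physical
#' units.  One bead diameter \eqn{\sigma_{LJ}} corresponds to 3 nm, the
#' effective diameter of B-DNA at physiological ionic strength; one energy
#' unit \eqn{\epsilon_0} corresponds to \eqn{1\,k_B T} (4e-21 J).
#'
#' @param length_unit physical length per sigma_LJ, in nm (default 3).
#' @param energy_unit physical energy per epsilon_0, in J (default 4e-21).
#' @param bp_per_bead base pairs represented by one bead (default
#'   3000/334, about 8.98).
#' @return An object of class `reduced_units`.
#' @examples
#' u <- reduced_units()
#' u$length_unit * 334 / pi # rough diameter (nm) of a 334-bead circle
#' @export
reduced_units <- function(length_unit = 3, energy_unit = 4e-21,
                          bp_per_bead = 3000 / 334) {
  stopifnot(length_unit > 0, energy_unit > 0, bp_per_bead > 0)
  structure(list(length_unit = length_unit, energy_unit = energy_unit,
                 bp_per_bead = bp_per_bead),
            class = "reduced_units")
}

#' Ring topology specification
#'
#' Describes one circular molecule: its discretisation and imposed linking
#' deficit.  The default mirrors a 3 kb plasmid modelled as 334 beads of
#' 3 nm, studied at linking deficits of 0, -7 and -14 turns.
#'
#' @param n_beads number of beads in the ring (default 334).
#' @param delta_lk signed linking-number deficit in turns (0, -7 or -14 in
#'   the reference conditions).  Use `NA` for a nicked (torsionally
#'   unconstrained) ring.
#' @param n_bp number of base pairs represented (default 3000).
#' @param helical_repeat base pairs per helical turn (default 10.5).
#' @return An object of class `ring_topology`.
#' @examples
#' ring_topology(delta_lk = -7)
#' @export
ring_topology <- function(n_beads = 334, delta_lk = 0, n_bp = 3000,
                          helical_repeat = 10.5) {
  stopifnot(n_beads >= 3, n_bp > 0, helical_repeat > 0)
  if (!is.na(delta_lk) && delta_lk != round(delta_lk))
    stop("delta_lk must be an integer number of turns (or NA for nicked)")
  structure(list(n_beads = as.integer(n_beads), delta_lk = delta_lk,
                 n_bp = n_bp, helical_repeat = helical_repeat),
            class = "ring_topology")
}

#' @export
print.ring_topology <- function(x, ...) {
  lk <- if (is.na(x$delta_lk)) "nicked (torsionally unconstrained)"
        else sprintf("deltaLk = %+d (sigma = %.4f)", x$delta_lk,
                     supercoiling_density(x$delta_lk, x$n_bp,
                                          x$helical_repeat))
  cat(sprintf("<ring_topology> %d beads, %d bp, %s\n",
              x$n_beads, round(x$n_bp), lk))
  invisible(x)
}

#' Coarse-grained DNA force field
#'
#' Energy parameters of the bead-spring DNA model, in reduced units
#' (sigma_LJ = 1, kT = epsilon_0 = 1):
#' \itemize{
#'   \item purely repulsive truncated Lennard-Jones excluded volume with
#'     `r_cut_rep = 1` sigma (the potential vanishes at the cutoff),
#'   \item harmonic bonds of rest length 1 sigma,
#'   \item bending energy `eps_bend * (1 - cos theta)` per junction;
#'     `eps_bend = 17` gives a persistence length of about 50 nm
#'     (see [persistence_length()]),
#'   \item harmonic twist energy `(k_twist/2) * phi^2` per junction; the
#'     default `k_twist = 31.7` corresponds to a torsional persistence
#'     length of about 95 nm of DNA,
#'   \item an attractive truncated-and-shifted Lennard-Jones well of depth
#'     `ep_eps = 8` kT and cutoff 2 sigma for the enhancer-promoter pair.
#' }
#'
#' @param eps_rep,r_cut_rep excluded-volume well scale and cutoff.
#' @param k_bond,r0_bond bond stiffness and rest length.
#' @param eps_bend bending stiffness (energy per junction).
#' @param k_twist twist stiffness (energy per squared radian per junction).
#' @param ep_eps,ep_rcut enhancer-promoter well depth and cutoff.
#' @return An object of class `force_field`.
#' @examples
#' ff <- force_field()
#' persistence_length(ff$eps_bend) # ~49.5 nm
#' @export
force_field <- function(eps_rep = 1, r_cut_rep = 1,
                        k_bond = 800, r0_bond = 1,
                        eps_bend = 17, k_twist = 31.7,
                        ep_eps = 8, ep_rcut = 2) {
  stopifnot(eps_rep >= 0, r_cut_rep > 0, k_bond >= 0, r0_bond > 0,
            eps_bend >= 0, k_twist >= 0, ep_eps >= 0, ep_rcut > 0)
  structure(list(eps_rep = eps_rep, r_cut_rep = r_cut_rep,
                 k_bond = k_bond, r0_bond = r0_bond,
                 eps_bend = eps_bend, k_twist = k_twist,
                 ep_eps = ep_eps, ep_rcut = ep_rcut),
            class = "force_field")
}

#' Worm-like chain persistence length of the bending potential
#'
#' For the discrete bending energy \eqn{\kappa (1 - \cos\theta)} per
#' junction at kT = 1, consecutive tangents satisfy
#' \eqn{\langle\cos\theta\rangle = \coth\kappa - 1/\kappa}, so
#' tangent-tangent correlations decay as
#' \eqn{\exp(-s\, b / L_p)} with
#' \eqn{L_p = -b / \ln(\coth\kappa - 1/\kappa)}.
#' At \eqn{\kappa = 17} and b = 3 nm this gives about 49.5 nm, the
#' calibration of the model to the 50 nm persistence length of B-DNA.
#'
#' @param eps_bend bending stiffness kappa in units of kT.
#' @param bond bond length b (default 1 sigma_LJ; pass 3 for nm).
#' @return Persistence length in the units of `bond`.
#' @examples
#' persistence_length(17, bond = 3) # nm
#' @export
persistence_length <- function(eps_bend, bond = 1) {
  if (eps_bend <= 0) stop("bending stiffness must be positive")
  avg_cos <- 1 / tanh(eps_bend) - 1 / eps_bend
  -bond / log(avg_cos)
}

#' Supercoiling density from the linking deficit
#'
#' \eqn{\sigma = \Delta Lk / (n_{bp} / h)} with h the helical repeat.
#' Deficits of -7 and -14 turns on a 3000 bp ring at 10.5 bp/turn give
#' sigma of about -0.025 and -0.05.
#'
#' @param delta_lk linking deficit in turns.
#' @param n_bp base-pair count.
#' @param helical_repeat base pairs per helical turn (default 10.5).
#' @return Dimensionless supercoiling density.
#' @examples
#' supercoiling_density(-7, 3000)  # ~ -0.025
#' supercoiling_density(-14, 3000) # ~ -0.05
#' @export
supercoiling_density <- function(delta_lk, n_bp, helical_repeat = 10.5) {
  stopifnot(n_bp > 0, helical_repeat > 0)
  delta_lk / (n_bp / helical_repeat)
}
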