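#' Excluded-volume (repulsive) energy
#'
#' Purely repulsive truncated Lennard-Jones energy
#' \eqn{U = \sum 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} over all
#' non-bonded bead pairs with \eqn{r < r_{cut} = 1\,\sigma}; the plain LJ
#' form vanishes at \eqn{r = \sigma}, so the truncated potential is
#' continuous (and zero) at the cutoff.  Distances use the minimum-image
#' convention when a finite box is given.  Overlapping beads trigger an
#' energy/force cap which is reported through the `capped` attribute.
#'
#' @param pos n x 3 coordinate matrix, or a [ring_conformation()], or a
#'   list of conformations (multi-molecule system).
#' @param ff a [force_field()].
#' @param box periodic box edge (`Inf` or `NA` for none).
#' @return Energy in epsilon_0, with attribute `capped` (logical).
#' @examples
#' p <- rbind(c(0, 0, 0), c(0.9, 0, 0), c(1.8, 0, 0))
#' energy_repulsive(list(ring_conformation(p, closed = FALSE)))
#' @export
energy_repulsive <- function(pos, ff = force_field(), box = Inf) {
  sys <- as_chain_set(pos)
  res <- cpp_energy_repulsive(sys$pos, if (is.finite(box)) box else -1,
                              sys$len, sys$closed, ff$eps_rep, ff$r_cut_rep)
  structure(res$energy, capped = res$capped)
}

#' Bending energy of one molecule
#'
#' \eqn{U = \kappa \sum_i (1 - \cos\theta_i)} over junction angles between
#' consecutive bond vectors; a straight junction costs nothing, a right
#' angle costs kappa.
#'
#' @param pos n x 3 coordinate matrix or [ring_conformation()].
#' @param ff a [force_field()].
#' @param closed treat the chain as a closed ring (ignored when `pos` is a
#'   conformation).
#' @return Energy in epsilon_0.
#' @export
energy_bend <- function(pos, ff = force_field(), closed = TRUE) {
  if (inherits(pos, "ring_conformation")) {
    closed <- pos$closed
    pos <- pos$pos
  }
  cpp_energy_bend(as.matrix(pos), closed, ff$eps_bend)
}

#' Bond (stretching) energy of one molecule
#'
#' Harmonic bonds: \eqn{U = \sum (k/2)(r_i - r_0)^2}.
#'
#' @inheritParams energy_bend
#' @return Energy in epsilon_0.
#' @export
energy_bond <- function(pos, ff = force_field(), closed = TRUE) {
  if (inherits(pos, "ring_conformation")) {
    closed <- pos$closed
    pos <- pos$pos
  }
  cpp_energy_bond(as.matrix(pos), closed, ff$k_bond, ff$r0_bond)
}

#' Twist energy of a torsionally constrained ring
#'
#' Harmonic in the per-junction excess-twist angle:
#' \eqn{U = \sum_i (k_t/2)\,\phi_i^2}.  The angles are the ribbon twist of
#' the material frame field, measured junction by junction at mid-edge
#' reference frames (the frame of the incoming edge is parallel-transported
#' across the junction before the signed rotation to the outgoing frame is
#' read off), a construction that stays well-defined up to 180-degree
#' bends.
#'
#' @param conf a [ring_conformation()] with twist angles populated.
#' @param ff a [force_field()].
#' @return Energy in epsilon_0.
#' @examples
#' conf <- twisted_circle(334, -7)
#' energy_twist(conf) # 334 * (k/2) * (2*pi*7/334)^2
#' @export
energy_twist <- function(conf, ff = force_field()) {
  stopifnot(inherits(conf, "ring_conformation"))
  if (is.null(conf$twist))
    stop("conformation carries no twist angles (nicked/unconstrained ring)")
  sum(0.5 * ff$k_twist * conf$twist^2)
}

# normalize pos / conformation / list-of-conformations to flat chain set
as_chain_set <- function(x) {
  if (is.matrix(x)) x <- list(ring_conformation(x))
  if (inherits(x, "ring_conformation")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1),
                                   "ring_conformation")))
  list(pos = do.call(rbind, lapply(x, `[[`, "pos")),
       len = vapply(x, function(r) nrow(r$pos), integer(1)),
       closed = vapply(x, `[[`, logical(1), "closed"))
}
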