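#' Thickness-probe parameters
#'
#' Controls for the tangent-sphere intra-molecular thickness probe.  A
#' short window of chain around the probed bead is ignored so that local
#' curvature does not trivially cap the probe; the default half-width of 10
#' beads (about 30 nm) stays below one persistence length.
#'
#' @param exclusion_halfwidth beads ignored on each side of the probed bead
#'   (same chain only; >= 2).
#' @param n_azimuth number of probe directions around the local tangent
#'   (>= 8).
#' @param max_radius probe-radius cap in sigma_LJ.
#' @param include_other_rings should beads of other molecules obstruct the
#'   probe (the natural choice in crowded systems)?
#' @param tol bisection tolerance on the probe radius (sigma_LJ).
#' @return An object of class `thickness_params`.
#' @export
thickness_params <- function(exclusion_halfwidth = 10, n_azimuth = 36,
                             max_radius = 15, include_other_rings = TRUE,
                             tol = 1e-3) {
  stopifnot(exclusion_halfwidth >= 2, n_azimuth >= 8, max_radius > 0,
            tol > 0)
  structure(list(exclusion_halfwidth = as.integer(exclusion_halfwidth),
                 n_azimuth = as.integer(n_azimuth),
                 max_radius = max_radius,
                 include_other_rings = include_other_rings, tol = tol),
            class = "thickness_params")
}

#' Local intra-molecular thickness at one bead
#'
#' Diameter of the largest sphere that is tangent to the chain at the
#' probed bead and can be placed at \emph{every} azimuthal angle around the
#' local tangent without intersecting the rest of the chain (and, by
#' default, any other molecule): for each azimuth the largest clear probe
#' radius is found by bisection, and the thickness is
#' `2 * min(rho) + sigma`, capped at `2 * max_radius + sigma`.  The probe
#' sphere sits externally tangent to the chain cylinder (centre offset
#' `rho + sigma/2`), so two touching strands give a thickness of exactly
#' one bead diameter.
#'
#' @param confs a [ring_conformation()] or list of them (all molecules that
#'   may obstruct the probe), with unwrapped coordinates.
#' @param ring which molecule to probe (index into `confs`).
#' @param bead bead index within that molecule (1-based).  Open-chain
#'   endpoints have no tangent and are rejected.
#' @param params a [thickness_params()].
#' @param box periodic box edge for minimum-image obstruction distances
#'   (`Inf` for none).
#' @return Thickness in sigma_LJ (>= 1).
#' @examples
#' strands <- parallel_strands(d = 1, length = 21)
#' local_thickness(strands, ring = 1, bead = 11) # 1: touching contact
#' @export
local_thickness <- function(confs, ring = 1, bead, params = thickness_params(),
                            box = Inf) {
  if (inherits(confs, "ring_conformation")) confs <- list(confs)
  sys <- as_chain_set(confs)
  off <- c(0L, cumsum(sys$len))
  stopifnot(ring >= 1, ring <= length(sys$len),
            bead >= 1, bead <= sys$len[ring])
  cpp_local_thickness(sys$pos, sys$len, sys$closed,
                      off[ring] + bead - 1L,
                      params$exclusion_halfwidth, params$n_azimuth,
                      params$max_radius, params$tol,
                      params$include_other_rings,
                      if (is.finite(box)) box else -1)
}

#' Thickness of every (interior) bead of one molecule
#'
#' @inheritParams local_thickness
#' @param stride probe every `stride`-th bead.
#' @return Numeric vector of thickness values.
#' @export
molecule_thickness <- function(confs, ring = 1, params = thickness_params(),
                               box = Inf, stride = 1) {
  if (inherits(confs, "ring_conformation")) confs <- list(confs)
  n <- nrow(confs[[ring]]$pos)
  beads <- if (confs[[ring]]$closed) seq(1, n, by = stride)
           else seq(2, n - 1, by = stride)
  vapply(beads, function(b) local_thickness(confs, ring, b, params, box),
         numeric(1))
}

#' Pooled thickness distribution over a trajectory
#'
#' Applies the tangent-sphere probe to every sampled bead of every molecule
#' in the (equilibrated part of a) trajectory and pools the values into a
#' frequency density profile with summary statistics.
#'
#' @param traj an `sc_trajectory` from [bd_run()] or [mc_sample()].
#' @param params a [thickness_params()].
#' @param frames which frame indices to analyse (default all).
#' @param stride bead stride within each molecule.
#' @param bins passed to [frequency_density()].
#' @return List with `values`, `profile` (data.frame), `mean` and `mode`
#'   (bin centre of the density maximum).
#' @export
thickness_ensemble <- function(traj, params = thickness_params(),
                               frames = NULL, stride = 1, bins = NULL) {
  stopifnot(inherits(traj, "sc_trajectory"))
  if (is.null(frames)) frames <- seq_along(traj$frames)
  vals <- unlist(lapply(frames, function(f) {
    confs <- trajectory_conformations(traj, f)
    unlist(lapply(seq_along(confs), function(r)
      molecule_thickness(confs, r, params, box = traj$box, stride = stride)))
  }))
  prof <- frequency_density(vals, bins)
  list(values = vals, profile = prof, mean = mean(vals),
       mode = prof$bin_center[which.max(prof$density)])
}
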