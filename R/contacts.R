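#' Enhancer-promoter interaction specification
#'
#' Two beads of the same molecule carrying a mutual short-range attraction:
#' a truncated Lennard-Jones well of depth 8 kT cut (and shifted to zero)
#' at two bead diameters.  On the 334-bead ring the sites sit 167 beads
#' apart, i.e. diametrically opposed along the contour.  The pair is
#' counted as in contact when the centre-centre distance is below 2 sigma
#' (surface-to-surface below one bead diameter).
#'
#' @param enhancer_bead,promoter_bead 1-based bead indices.
#' @param eps well depth (epsilon_0).
#' @param rcut interaction cutoff (sigma_LJ).
#' @param contact_dist centre-centre contact threshold (sigma_LJ).
#' @return An object of class `ep_spec`.
#' @export
ep_spec <- function(enhancer_bead = 1L, promoter_bead = 168L, eps = 8,
                    rcut = 2, contact_dist = 2) {
  stopifnot(enhancer_bead >= 1, promoter_bead >= 1,
            enhancer_bead != promoter_bead, eps >= 0, rcut > 0,
            contact_dist <= rcut + 1e-9)
  structure(list(enhancer_bead = as.integer(enhancer_bead),
                 promoter_bead = as.integer(promoter_bead),
                 eps = eps, rcut = rcut, contact_dist = contact_dist),
            class = "ep_spec")
}

#' Enhancer-promoter pair potential
#'
#' Full (attractive) Lennard-Jones with well depth `eps`, truncated at
#' `rcut` and shifted so the potential is continuously zero at and beyond
#' the cutoff.
#'
#' @param r centre-centre distance(s), sigma_LJ.
#' @param spec an [ep_spec()].
#' @return Energy in epsilon_0 (vectorised over `r`).
#' @examples
#' ep_energy(2^(1/6), ep_spec()) # well minimum: -8 + shift
#' ep_energy(2, ep_spec())       # 0 at the cutoff
#' @export
ep_energy <- function(r, spec = ep_spec()) {
  stopifnot(all(r > 0))
  shift <- 4 * spec$eps * (spec$rcut^-12 - spec$rcut^-6)
  u <- 4 * spec$eps * (r^-12 - r^-6) - shift
  ifelse(r < spec$rcut, u, 0)
}

#' Enhancer-promoter contact fraction of a trajectory
#'
#' Fraction of sampled frames in which the enhancer and promoter beads of
#' each molecule are closer than the contact threshold, averaged over
#' molecules, with a block-averaged standard error (blocks along time, so
#' the error estimate is robust to frame-to-frame correlation).
#'
#' @param traj an `sc_trajectory`.
#' @param spec an [ep_spec()].
#' @param frames frame indices to analyse (default all).
#' @param n_blocks number of time blocks for the standard error.
#' @return List with `fraction`, `se`, and the per-frame-per-molecule
#'   logical matrix `in_contact`.
#' @export
contact_fraction <- function(traj, spec = ep_spec(), frames = NULL,
                             n_blocks = 10) {
  stopifnot(inherits(traj, "sc_trajectory"))
  if (is.null(frames)) frames <- seq_along(traj$frames)
  nring <- length(traj$ring_len)
  off <- c(0L, cumsum(traj$ring_len))
  contact <- matrix(NA, length(frames), nring)
  for (k in seq_along(frames)) {
    p <- traj$frames[[frames[k]]]
    for (r in seq_len(nring)) {
      i <- off[r] + spec$enhancer_bead
      j <- off[r] + spec$promoter_bead
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      contact[k, r] <- d < spec$contact_dist
    }
  }
  per_frame <- rowMeans(contact)
  nb <- max(1, min(n_blocks, floor(length(per_frame) / 2)))
  blocks <- split(per_frame,
                  cut(seq_along(per_frame), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- if (length(bm) > 1) sd(bm) / sqrt(length(bm)) else NA_real_
  list(fraction = mean(per_frame), se = se, in_contact = contact)
}

#' Linear-control system for the enhancer-promoter assay
#'
#' Open chain with the same number of beads, the same genomic separation
#' between enhancer and promoter sites and the same mutual affinity as the
#' circular molecules, but no closure bond and no twist term: the control
#' that isolates the role of circularity (topological exclusion) in
#' crowding-stimulated contacts.
#'
#' @param spec an [ep_spec()].
#' @param n_beads chain length.
#' @return List with `conf` (an open, straight [ring_conformation()]) and
#'   `spec` (the unchanged [ep_spec()]).
#' @export
make_linear_control <- function(spec = ep_spec(), n_beads = 334L) {
  stopifnot(n_beads >= max(spec$enhancer_bead, spec$promoter_bead))
  z <- seq_len(n_beads) - (n_beads + 1) / 2
  conf <- ring_conformation(cbind(0, 0, z), closed = FALSE)
  list(conf = conf, spec = spec)
}
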