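#' Writhe of a closed ring
#'
#' Gauss double integral over the curve evaluated exactly segment pair by
#' segment pair with the closed-form solid-angle expression; the sum runs
#' over ordered pairs divided by 4 pi, so a planar curve has writhe 0 and a
#' mirror reflection flips the sign.  Adjacent segment pairs are skipped
#' (their contribution vanishes in the limit).
#'
#' @param pos closed-ring coordinate matrix (unwrapped) or a
#'   [ring_conformation()].
#' @return Dimensionless writhe.
#' @examples
#' writhe(planar_circle(64)) # 0
#' @export
writhe <- function(pos) {
  if (inherits(pos, "ring_conformation")) {
    if (!pos$closed) stop("writhe is defined for closed rings")
    pos <- pos$pos
  }
  cpp_writhe(as.matrix(pos))
}

#' Excess twist of a ring, in turns
#'
#' \eqn{Tw = \sum_i \phi_i / 2\pi} over the per-junction excess-twist
#' angles.
#'
#' @param conf a [ring_conformation()] with twist angles, or a numeric
#'   vector of per-junction angles in radians.
#' @return Twist in turns.
#' @export
twist <- function(conf) {
  phi <- if (inherits(conf, "ring_conformation")) conf$twist else conf
  if (is.null(phi))
    stop("conformation carries no twist angles (nicked/unconstrained ring)")
  sum(phi) / (2 * pi)
}

#' Topology record of a ring conformation
#'
#' Twist, writhe, their sum (the linking number relative to the relaxed
#' state) and the supercoiling density.
#'
#' @param conf a [ring_conformation()].
#' @param topo a [ring_topology()] supplying base-pair count and helical
#'   repeat for the supercoiling density.
#' @return A one-row data.frame with columns `tw`, `wr`, `lk`, `sigma`.
#' @examples
#' topology_record(twisted_circle(334, -7), ring_topology(delta_lk = -7))
#' @export
topology_record <- function(conf, topo = ring_topology()) {
  wr <- writhe(conf)
  tw <- if (is.null(conf$twist)) NA_real_ else twist(conf)
  lk <- tw + wr
  data.frame(tw = tw, wr = wr, lk = lk,
             sigma = supercoiling_density(lk, topo$n_bp,
                                          topo$helical_repeat))
}
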