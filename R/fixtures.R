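#' Planar circular ring
#'
#' Regular n-gon in the xy-plane with unit bond length by default; zero
#' excess twist.  The reference conformation of a torsionally relaxed
#' circular molecule: writhe is exactly zero.
#'
#' @param n number of beads.
#' @param radius circle radius; default gives bond length 1 sigma.
#' @return A closed [ring_conformation()] (no material frames).
#' @examples
#' writhe(planar_circle(64)) # 0
#' @export
planar_circle <- function(n, radius = 1 / (2 * sin(pi / n))) {
  stopifnot(n >= 3)
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring_conformation(cbind(radius * cos(th), radius * sin(th), 0))
}

#' Uniformly twisted planar circle
#'
#' Planar circle carrying a uniform excess twist that sums to `delta_lk`
#' turns: Tw = delta_lk, Wr = 0, so the full linking deficit sits in twist.
#' This is the topological initial condition of a supercoiled ring before
#' twist partitions into writhe.
#'
#' @param n number of beads.
#' @param delta_lk linking deficit in turns (integer).
#' @param radius circle radius; default gives bond length 1 sigma.
#' @return A closed [ring_conformation()] with material frames.
#' @examples
#' conf <- twisted_circle(334, -7)
#' twist(conf) + writhe(conf) # -7
#' @export
twisted_circle <- function(n, delta_lk, radius = 1 / (2 * sin(pi / n))) {
  set_ring_twist(planar_circle(n, radius), delta_lk)
}

#' Plectonemic ring of known writhe
#'
#' Deterministic interwound superhelix: two helical strands winding around
#' a straight axis, capped by semicircular apical loops, as in the
#' plectonemic arrangement of supercoiled DNA.  With `n_turns` interwound
#' turns the writhe is close to `-n_turns` for right-handed winding
#' (`handedness = 1`), the sign flipping with handedness.
#'
#' @param n number of beads (even; a few beads are consumed by the caps).
#' @param n_turns number of interwound superhelical turns.
#' @param superhelix_radius radius of the interwound helices (sigma_LJ).
#' @param pitch axial rise per superhelical turn (sigma_LJ).
#' @param handedness `1` (right-handed winding, negative writhe) or `-1`.
#' @return A closed [ring_conformation()].
#' @examples
#' abs(writhe(plectoneme(200, 5)) + 5) < 0.5
#' @export
plectoneme <- function(n, n_turns, superhelix_radius = 1.5, pitch = 6,
                       handedness = 1) {
  stopifnot(n >= 20, n_turns >= 1, superhelix_radius > 0, pitch > 0)
  stopifnot(handedness %in% c(-1, 1))
  if (pitch < 2 * superhelix_radius * 0.5)
    stop("pitch too small: superhelical strands would self-intersect")
  r <- superhelix_radius
  h <- pitch * n_turns            # axial extent of the interwound region
  # arc lengths: two helices + two semicircular caps of radius r
  len_helix <- sqrt(h^2 + (2 * pi * r * n_turns)^2)
  len_cap <- pi * r
  total <- 2 * len_helix + 2 * len_cap
  n_cap <- max(4L, round(n * len_cap / total))
  n_hel <- (n - 2 * n_cap) %/% 2
  n_hel2 <- n - 2 * n_cap - n_hel
  if (n_hel < 2 * n_turns * 4)
    stop("too few beads to resolve the requested superhelical turns")
  s <- handedness
  # strand 1: bottom to top
  t1 <- seq(0, 1, length.out = n_hel + 1)[-(n_hel + 1)]
  p1 <- cbind(r * cos(2 * pi * n_turns * t1),
              s * r * sin(2 * pi * n_turns * t1),
              h * t1)
  # top cap: semicircle joining strand 1 end to strand 2 start
  a1 <- 2 * pi * n_turns
  tc <- seq(0, 1, length.out = n_cap + 1)[-(n_cap + 1)]
  # rotate by pi around the axis while rising slightly: half-turn cap
  capang <- a1 + tc * pi
  p2 <- cbind(r * cos(capang), s * r * sin(capang),
              h + r * sin(tc * pi) * 0.5)
  # strand 2: top to bottom, offset by pi in phase
  t2 <- seq(1, 0, length.out = n_hel2 + 1)[-(n_hel2 + 1)]
  p3 <- cbind(r * cos(2 * pi * n_turns * t2 + pi),
              s * r * sin(2 * pi * n_turns * t2 + pi),
              h * t2)
  # bottom cap back to start
  capang2 <- pi + tc * pi
  p4 <- cbind(r * cos(capang2), s * r * sin(capang2),
              -r * sin(tc * pi) * 0.5)
  pos <- rbind(p1, p2, p3, p4)
  # resample to uniform bead spacing along the polygon
  pos <- resample_closed(pos, n)
  conf <- ring_conformation(pos)
  # guard: self-avoidance of the constructed geometry
  dmin <- min_self_distance(pos)
  if (dmin < 0.5)
    stop(sprintf(
      "self-intersecting plectoneme parameters (min distance %.2f sigma)",
      dmin))
  conf
}

# resample a closed polygonal curve to n equally spaced vertices
resample_closed <- function(pos, n) {
  m <- nrow(pos)
  seg <- sqrt(rowSums((pos[c(2:m, 1), ] - pos)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1]
  s_new <- total * (seq_len(n) - 1) / n
  idx <- findInterval(s_new, cum, rightmost.closed = TRUE)
  frac <- (s_new - cum[idx]) / seg[idx]
  nxt <- ifelse(idx == m, 1, idx + 1)
  pos[idx, , drop = FALSE] +
    (pos[nxt, , drop = FALSE] - pos[idx, , drop = FALSE]) * frac
}

# minimum distance between non-neighbouring beads of a closed ring
min_self_distance <- function(pos) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  sep <- pmin(sep, n - sep)
  min(d[sep > 2])
}

#' Point cloud on an ellipsoid shell
#'
#' Sample of n points on the surface of the ellipsoid with semiaxes
#' `a >= b >= c`, distributed as the affine image of a uniform spherical
#' shell (x = a v1, y = b v2, z = c v3 with v uniform on the unit
#' sphere).  This is the shell mass distribution whose second moments
#' satisfy the hollow-shell relations exactly
#' (\eqn{\langle x^2\rangle = a^2/3}, cyclic), so
#' [inertial_ellipsoid()] applied to the cloud recovers (a, b, c) up to
#' sampling noise.  (A cloud with uniform surface *area* density has
#' different moments and would not satisfy the round-trip contract.)
#'
#' @param a,b,c semiaxes, `a >= b >= c > 0`.
#' @param n number of points.
#' @param seed RNG seed (deterministic fixture).
#' @return n x 3 matrix of coordinates.
#' @examples
#' axes <- inertial_ellipsoid(ellipsoid_shell(4, 2, 1, 5000, seed = 1))
#' @export
ellipsoid_shell <- function(a, b, c, n, seed = 1) {
  stopifnot(a >= b, b >= c, c > 0, n >= 4)
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  cbind(a * v[, 1], b * v[, 2], c * v[, 3])
}

#' Equilibrium-sampled free semiflexible chain
#'
#' Open chain drawn exactly from the Boltzmann distribution of the ideal
#' (phantom) bead-spring model: bond lengths from the harmonic-bond
#' density \eqn{p(r) \propto r^2 \exp(-k(r - r_0)^2/2)} and junction
#' angles from \eqn{p(\theta) \propto \sin\theta\,\exp(\kappa\cos\theta)}
#' (inverse-CDF sampling).  Used to start dynamics runs at equilibrium,
#' e.g. for persistence-length calibration, so no relaxation from an
#' atypical state is needed.
#'
#' @param n number of beads.
#' @param eps_bend bending stiffness kappa.
#' @param k_bond,r0 bond stiffness and rest length.
#' @param seed RNG seed (`NA` to continue the ambient stream).
#' @return An open [ring_conformation()].
#' @export
equilibrium_chain <- function(n, eps_bend = 17, k_bond = 800, r0 = 1,
                              seed = NA) {
  stopifnot(n >= 2)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  # bond lengths: rejection from the Gaussian envelope (r^2 Jacobian)
  rmax <- r0 + 4 / sqrt(k_bond)
  draw_r <- function(m) {
    out <- numeric(0)
    while (length(out) < m) {
      r <- rnorm(2 * m, r0, 1 / sqrt(k_bond))
      keep <- r > 0 & runif(2 * m) < (r / rmax)^2
      out <- c(out, r[keep])
    }
    out[seq_len(m)]
  }
  # junction angles: inverse CDF of sin(t) exp(k cos t) on [0, pi]
  kap <- eps_bend
  u <- runif(n - 2)
  cost <- 1 + log(u + (1 - u) * exp(-2 * kap)) / kap
  psi <- runif(n - 2, 0, 2 * pi)
  pos <- matrix(0, n, 3)
  t_cur <- c(0, 0, 1)
  blen <- draw_r(n - 1)
  pos[2, ] <- pos[1, ] + blen[1] * t_cur
  for (i in seq_len(n - 2)) {
    # rotate the tangent by theta about a random perpendicular azimuth
    ref <- if (abs(t_cur[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * t_cur) * t_cur
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t_cur[2] * e1[3] - t_cur[3] * e1[2],
            t_cur[3] * e1[1] - t_cur[1] * e1[3],
            t_cur[1] * e1[2] - t_cur[2] * e1[1])
    sint <- sqrt(pmax(0, 1 - cost[i]^2))
    t_cur <- cost[i] * t_cur +
      sint * (cos(psi[i]) * e1 + sin(psi[i]) * e2)
    t_cur <- t_cur / sqrt(sum(t_cur^2))
    pos[i + 2, ] <- pos[i + 1, ] + blen[i + 1] * t_cur
  }
  ring_conformation(pos, closed = FALSE)
}

#' Two parallel straight strands
#'
#' Pair of straight bead rows at centre-centre distance `d`, used to probe
#' the close-apposition limit of the intra-molecular thickness: at
#' `d = 1` sigma (touching) the thickness at interior beads equals one bead
#' diameter.
#'
#' @param d centre-centre distance between the strands (>= 1 sigma).
#' @param length number of beads per strand.
#' @return List of two open [ring_conformation()] chains.
#' @export
parallel_strands <- function(d, length = 21) {
  stopifnot(d >= 1, length >= 3)
  z <- seq_len(length) - (length + 1) / 2
  list(ring_conformation(cbind(0, 0, z), closed = FALSE, ring_id = 1L),
       ring_conformation(cbind(d, 0, z), closed = FALSE, ring_id = 2L))
}
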