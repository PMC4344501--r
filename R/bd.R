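#' Brownian-dynamics run protocol
#'
#' Integration and sampling parameters of the overdamped (Euler-Maruyama)
#' propagator at kT = 1.  The default time step of 5e-4 reduced time units
#' leaves a comfortable stability margin at the default bond stiffness of
#' 800; steps above 1e-3 are rejected.
#'
#' @param dt integration step (reduced time).
#' @param gamma translational friction per bead (reduced).
#' @param gamma_t rotational friction of the material frame about the
#'   local tangent.
#' @param n_steps number of integration steps.
#' @param sample_every store a frame every this many steps.
#' @param target_phi target volume fraction for compression protocols.
#' @param compression_rate fractional box shrink per compression interval.
#' @param compression_interval relaxation steps between shrinks.
#' @param seed RNG seed (`NA` to continue the ambient RNG stream).
#' @return An object of class `run_protocol`.
#' @export
run_protocol <- function(dt = 5e-4, gamma = 1, gamma_t = 1,
                         n_steps = 1e5, sample_every = 1000,
                         target_phi = 0, compression_rate = 0.005,
                         compression_interval = 1e4, seed = 1) {
  stopifnot(dt > 0, dt <= 1e-3, gamma > 0, gamma_t > 0, n_steps >= 0,
            sample_every >= 1, target_phi >= 0, target_phi <= 0.3,
            compression_rate > 0, compression_rate < 0.1)
  structure(list(dt = dt, gamma = gamma, gamma_t = gamma_t,
                 n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 target_phi = target_phi,
                 compression_rate = compression_rate,
                 compression_interval = as.integer(compression_interval),
                 seed = seed),
            class = "run_protocol")
}

# Hamiltonian cycle through an R x C grid (R even, C >= 2): row 1 left to
# right, rows 2..R boustrophedon over columns 2..C, return up column 1.
grid_cycle <- function(R, C) {
  stopifnot(R %% 2 == 0, R >= 2, C >= 2)
  path <- lapply(seq_len(C), function(cc) c(1, cc))
  for (r in 2:R) {
    cols <- if (r %% 2 == 0) C:2 else 2:C
    path <- c(path, lapply(cols, function(cc) c(r, cc)))
  }
  c(path, lapply(R:2, function(r) c(r, 1)))
}

# compact space-filling fold of a closed ring into a rectangular cell
# `cdim`, centred at the origin: a bundle of straight passes along the
# longest cell axis, visited along a Hamiltonian cycle of the pass grid
# with rounded U-turns, so the fold closes without an external return
# path.  Used to seed crowded systems without inter-ring overlap/linking.
meander_ring <- function(n, cdim, sp = 1.05) {
  gap <- 0.95                        # clearance to neighbouring cells
  turn <- pi * sp / 2                # contour consumed per U-turn
  bulge <- 0.85 * sp                 # U-turn extension past the pass ends
  ax <- which.max(cdim)
  perp <- setdiff(1:3, ax)
  lpass_max <- cdim[ax] - gap - 2 * bulge - 1   # -1: bead radius both ends
  if (lpass_max < 1.5) stop("cell too small to fold a ring into")
  nmax <- vapply(cdim[perp], function(w)
    max(0, floor((w - gap - 1) / sp) + 1), numeric(1))
  if (any(nmax < 2)) stop("cell cross-section too small for the fold")
  need <- ceiling(n / (lpass_max + turn))
  best <- NULL
  for (n1 in 2:nmax[1]) for (n2 in 2:nmax[2]) {
    if (n1 * n2 < need) next
    if (n1 %% 2 == 1 && n2 %% 2 == 1) next
    if (is.null(best) || n1 * n2 < prod(best)) best <- c(n1, n2)
  }
  if (is.null(best))
    stop("volume fraction too high: cannot fold ring into its cell")
  if (best[1] %% 2 == 1) best <- rev(best)   # cycle needs even row count
  npass <- prod(best)
  lpass <- min(max(n / npass - turn, 1.2), lpass_max)
  cyc <- grid_cycle(best[1], best[2])
  centers <- lapply(cyc, function(rc)
    (rc - (best + 1) / 2) * sp)
  pts <- list()
  dir <- 1
  for (p in seq_along(centers)) {
    uv <- centers[[p]]
    e_in <- numeric(3); e_out <- numeric(3)
    e_in[perp] <- uv; e_out[perp] <- uv
    e_in[ax] <- -dir * lpass / 2
    e_out[ax] <- dir * lpass / 2
    if (p > 1) {                     # U-turn bulge from the previous pass
      prev <- pts[[length(pts)]]
      mid <- (prev + e_in) / 2
      mid[ax] <- mid[ax] - dir * bulge   # previous pass ended on -dir side
      pts[[length(pts) + 1]] <- mid
    }
    pts[[length(pts) + 1]] <- e_in
    pts[[length(pts) + 1]] <- e_out
    dir <- -dir
  }
  # closing U-turn between the last pass end and the first pass start
  first <- pts[[1]]; last <- pts[[length(pts)]]
  mid <- (first + last) / 2
  mid[ax] <- mid[ax] - bulge         # both endpoints sit on the -ax side
  pts[[length(pts) + 1]] <- mid
  resample_closed(do.call(rbind, pts), n)
}

#' Initialise a multi-ring system
#'
#' Places `m_rings` copies of the ring on a cubic lattice.  Dilute systems
#' (`phi = 0`) get planar circles in an infinite box (molecules do not
#' interact and are propagated independently).  Crowded systems get a box
#' of edge \eqn{L = (m\, n\, (\pi/6) / \phi)^{1/3}} and, since a planar
#' circle does not fit inside a lattice cell, each ring starts as a
#' compact space-filling fold inside its own cell (no overlap, no
#' linking).  For `delta_lk != 0` the material frame is wound so that the
#' ring's linking number equals `delta_lk` exactly, wherever its initial
#' writhe sits; nicked rings (`delta_lk = NA`) carry no frames.
#'
#' @param topo a [ring_topology()].
#' @param m_rings number of molecules (20 in the reference conditions).
#' @param phi target volume fraction in `[0, 0.3]`.
#' @param seed RNG seed for the (reproducible) orientation shuffling.
#' @return A [system_state()].
#' @examples
#' st <- init_system(ring_topology(delta_lk = -7), m_rings = 2, phi = 0.1)
#' volume_fraction(st)
#' @export
init_system <- function(topo, m_rings = 20, phi = 0.20, seed = 1) {
  stopifnot(inherits(topo, "ring_topology"), m_rings >= 1,
            phi >= 0, phi <= 0.3)
  n <- topo$n_beads
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  torsion <- !is.na(topo$delta_lk)
  if (phi == 0) {
    gap <- 3 / sin(pi / n)           # three diameters apart along x
    rings <- lapply(seq_len(m_rings), function(r) {
      conf <- planar_circle(n)
      conf$pos[, 1] <- conf$pos[, 1] + (r - 1) * gap
      conf$ring_id <- r
      if (torsion) conf <- set_ring_twist(conf, topo$delta_lk)
      conf
    })
    return(system_state(rings, box_length = Inf))
  }
  L <- (m_rings * n * (pi / 6) / phi)^(1 / 3)
  # partition the box into a lattice of rectangular cells (>= m of them)
  # and build one compact fold that fits a cell; elongated cells are fine,
  # the fold aligns its passes with the longest cell axis
  base <- NULL
  triples <- expand.grid(k1 = 1:m_rings, k2 = 1:m_rings, k3 = 1:m_rings)
  triples <- triples[triples$k1 * triples$k2 * triples$k3 >= m_rings &
                     triples$k1 * triples$k2 * triples$k3 <= 2 * m_rings, ]
  triples <- triples[order(triples$k1 * triples$k2 * triples$k3,
                           apply(triples, 1, function(k) diff(range(k)))), ]
  for (i in seq_len(nrow(triples))) {
    kk <- as.numeric(triples[i, ])
    cdim <- L / kk
    cand <- tryCatch({
      R <- 1 / (2 * sin(pi / n))     # planar circle if it fits the cell
      if (2 * R + 1 + 0.95 <= min(cdim)) {
        planar_circle(n)$pos
      } else {
        meander_ring(n, cdim)
      }
    }, error = function(e) NULL)
    if (!is.null(cand) && min_self_distance(cand) >= 0.85) {
      base <- cand
      kgrid <- kk
      break
    }
  }
  if (is.null(base))
    stop("volume fraction too high: no non-overlapping placement found")
  cells <- expand.grid(ix = seq_len(kgrid[1]), iy = seq_len(kgrid[2]),
                       iz = seq_len(kgrid[3]))
  cells <- cells[seq_len(m_rings), , drop = FALSE]
  cdim <- L / kgrid
  rings <- lapply(seq_len(m_rings), function(r) {
    center <- (as.numeric(cells[r, ]) - 0.5) * cdim
    conf <- ring_conformation(sweep(base, 2, center, "+"), ring_id = r)
    if (torsion) conf <- set_ring_twist(conf, topo$delta_lk)
    conf
  })
  # wrap into the box
  wrapped <- wrap_coordinates(lapply(rings, `[[`, "pos"), L)
  for (r in seq_len(m_rings)) rings[[r]]$pos <- wrapped$pos[[r]]
  st <- system_state(rings, box_length = L, image_flags = wrapped$flags)
  en <- energy_repulsive(unwrap_to_confs(st), box = L)
  if (isTRUE(attr(en, "capped")))
    stop("volume fraction too high: overlapping placement")
  st
}

# system_state -> list of conformations with unwrapped coordinates
unwrap_to_confs <- function(state) {
  up <- unwrap_molecules(state)
  lapply(seq_along(state$rings), function(i) {
    conf <- state$rings[[i]]
    conf$pos <- up[[i]]
    conf
  })
}

#' Propagate a system by Brownian dynamics
#'
#' Overdamped Euler-Maruyama integration
#' \eqn{r \leftarrow r + (dt/\gamma) F + \sqrt{2 dt/\gamma}\,\xi} at
#' kT = 1, with forces from the full force field (bonds, bending, ribbon
#' twist for torsionally constrained rings, truncated-LJ excluded volume
#' under the minimum-image convention, and the optional enhancer-promoter
#' well).  Material frames are co-rotated with their local tangent
#' (parallel transport) each step and relaxed by torsional torques through
#' a rotational Langevin update, which conserves the ring's linking number
#' Lk = Tw + Wr up to numerical round-off.
#'
#' Dilute systems (infinite box) with several molecules are propagated as
#' independent single-molecule simulations (identical statistics, no
#' inter-molecular interactions by construction).
#'
#' @param state a [system_state()].
#' @param ff a [force_field()].
#' @param proto a [run_protocol()].
#' @param ep optional [ep_spec()] applied within every molecule.
#' @param excluded_volume disable to simulate phantom chains (used for
#'   ideal-chain calibration runs).
#' @return An `sc_trajectory`; the final state (with frames/twist carried
#'   over) is attached as `$final_state`.
#' @export
bd_run <- function(state, ff = force_field(), proto = run_protocol(),
                   ep = NULL, excluded_volume = TRUE) {
  stopifnot(inherits(state, "system_state"))
  if (!is.null(proto$seed) && !is.na(proto$seed)) set.seed(proto$seed)
  L <- state$box_length
  nring <- length(state$rings)

  if (!is.finite(L) && nring > 1) {
    # dilute: propagate molecules independently and merge
    parts <- lapply(seq_len(nring), function(r) {
      sub <- system_state(state$rings[r], Inf, state$image_flags[r],
                          state$step)
      proto_r <- proto
      proto_r$seed <- NA             # continue the ambient stream
      bd_run(sub, ff, proto_r, ep = ep, excluded_volume = excluded_volume)
    })
    nf <- length(parts[[1]]$frames)
    frames <- lapply(seq_len(nf), function(k)
      do.call(rbind, lapply(parts, function(tr) tr$frames[[k]])))
    twist <- if (!is.null(parts[[1]]$twist))
      lapply(seq_len(nf), function(k)
        unlist(lapply(parts, function(tr) tr$twist[[k]])))
    traj <- sc_trajectory(
      frames, twist = twist,
      ring_len = vapply(state$rings, function(r) nrow(r$pos), integer(1)),
      closed = vapply(state$rings, `[[`, logical(1), "closed"),
      torsion = vapply(state$rings,
                       function(r) !is.null(r$frames), logical(1)),
      box = Inf, steps = parts[[1]]$steps,
      rg = do.call(cbind, lapply(parts, `[[`, "rg")),
      energy = Reduce(`+`, lapply(parts, `[[`, "energy")),
      metadata = list(ff = ff, protocol = proto, ep = ep))
    traj$final_state <- system_state(
      lapply(parts, function(tr) tr$final_state$rings[[1]]),
      Inf, step = state$step + proto$n_steps)
    for (r in seq_len(nring)) traj$final_state$rings[[r]]$ring_id <- r
    return(traj)
  }

  confs <- unwrap_to_confs(state)
  sys <- as_chain_set(confs)
  torsion <- vapply(confs, function(r) !is.null(r$frames), logical(1))
  frames_mat <- NULL
  if (any(torsion)) {
    frames_mat <- do.call(rbind, lapply(confs, function(r) {
      if (is.null(r$frames)) matrix(0, nrow(r$pos), 3) else r$frames
    }))
  }
  ep_pairs <- matrix(integer(), 0, 2)
  if (!is.null(ep)) {
    off <- c(0L, cumsum(sys$len))
    ok <- sys$len >= pmax(ep$enhancer_bead, ep$promoter_bead)
    ep_pairs <- cbind(off[which(ok)] + ep$enhancer_bead - 1L,
                      off[which(ok)] + ep$promoter_bead - 1L)
  }
  res <- cpp_bd_run(sys$pos, sys$len, sys$closed, torsion, frames_mat,
                    if (is.finite(L)) L else -1,
                    ff$eps_rep, ff$r_cut_rep, ff$k_bond, ff$r0_bond,
                    ff$eps_bend, ff$k_twist,
                    ep_pairs, if (is.null(ep)) 0 else ep$eps,
                    if (is.null(ep)) 2 else ep$rcut,
                    excluded_volume,
                    proto$dt, proto$gamma, proto$gamma_t,
                    proto$n_steps, proto$sample_every)
  nf <- length(res$samples)
  steps <- state$step + proto$sample_every * seq_len(nf)
  twist <- if (any(torsion))
    lapply(res$sample_twist, function(v) v) else NULL
  traj <- sc_trajectory(res$samples, twist = twist, ring_len = sys$len,
                        closed = sys$closed, torsion = torsion,
                        box = L, steps = if (nf) steps else integer(),
                        rg = res$rg, energy = res$energy,
                        metadata = list(ff = ff, protocol = proto, ep = ep))
  # final state: rewrap, carry frames and twist angles forward
  off <- c(0L, cumsum(sys$len))
  pos_list <- lapply(seq_len(nring), function(r)
    res$pos[(off[r] + 1):off[r + 1], , drop = FALSE])
  wrapped <- wrap_coordinates(pos_list, L)
  rings <- lapply(seq_len(nring), function(r) {
    conf <- state$rings[[r]]
    conf$pos <- wrapped$pos[[r]]
    if (torsion[r]) {
      conf$frames <- res$frames[(off[r] + 1):off[r + 1], , drop = FALSE]
      up <- pos_list[[r]]
      conf$twist <- cpp_twist_angles(up, conf$frames)
    }
    conf
  })
  traj$final_state <- system_state(rings, L, wrapped$flags,
                                   step = state$step + proto$n_steps)
  traj
}

#' Compress a periodic system to a target volume fraction
#'
#' The crowding protocol: the box edge shrinks by `compression_rate` per
#' interval, molecule centroids are rescaled with the box (internal
#' coordinates untouched), and the system relaxes by Brownian dynamics
#' between shrinks.  The final shrink lands exactly on the target, so the
#' resulting volume fraction matches it to numerical precision.
#'
#' @param state a finite-box [system_state()].
#' @param target_phi target volume fraction (> current).
#' @param ff,proto,ep as in [bd_run()].
#' @param sampler relax between shrinks by Brownian dynamics (`"bd"`,
#'   `proto$compression_interval` steps) or Monte Carlo (`"mc"`,
#'   `mc_sweeps` sweeps — far cheaper per unit of shape relaxation, the
#'   practical choice when compressing from very dilute starts).
#' @param mc_sweeps MC sweeps per shrink stage when `sampler = "mc"`.
#' @param delta_lk per-molecule linking deficit for MC relaxation
#'   (`NA` = torsionally unconstrained).
#' @return The compressed (and relaxed) [system_state()].
#' @export
compress_box <- function(state, target_phi, ff = force_field(),
                         proto = run_protocol(), ep = NULL,
                         sampler = c("bd", "mc"), mc_sweeps = 150,
                         delta_lk = NA) {
  sampler <- match.arg(sampler)
  stopifnot(is.finite(state$box_length))
  if (!is.null(proto$seed) && !is.na(proto$seed)) set.seed(proto$seed)
  phi <- volume_fraction(state)
  if (target_phi <= phi + 1e-12) return(state)
  n_tot <- sum(vapply(state$rings, function(r) nrow(r$pos), integer(1)))
  L_target <- (n_tot * (pi / 6) / target_phi)^(1 / 3)
  proto_relax <- proto
  proto_relax$seed <- NA
  proto_relax$n_steps <- proto$compression_interval
  proto_relax$sample_every <- proto$compression_interval
  repeat {
    L_old <- state$box_length
    L_new <- max(L_old * (1 - proto$compression_rate), L_target)
    up <- unwrap_molecules(state)
    scaled <- lapply(up, function(p) {
      centroid <- colMeans(p) %% L_old    # box-relative centroid position
      sweep(p, 2, centroid * (L_new / L_old - 1), "+")
    })
    wrapped <- wrap_coordinates(scaled, L_new)
    rings <- state$rings
    for (r in seq_along(rings)) rings[[r]]$pos <- wrapped$pos[[r]]
    state <- system_state(rings, L_new, wrapped$flags, state$step)
    en <- energy_repulsive(unwrap_to_confs(state), ff, box = L_new)
    if (isTRUE(attr(en, "capped")))
      stop("compression rate too large: beads driven into the repulsive core")
    if (sampler == "bd") {
      traj <- bd_run(state, ff, proto_relax, ep = ep)
    } else {
      traj <- mc_sample(state, ff, n_sweeps = mc_sweeps,
                        sample_every = mc_sweeps, delta_lk = delta_lk,
                        ep = ep, seed = NA)
    }
    state <- traj$final_state
    if (L_new <= L_target + 1e-12) break
  }
  state
}

#' Detect equilibration from radius-of-gyration time series
#'
#' Scans windowed means of each molecule's Rg series and returns the first
#' frame index at which every molecule's windowed mean lies within one
#' standard error of that molecule's final-half mean.  A run is accepted
#' as equilibrated only if its length exceeds eight times the detected
#' equilibration time; otherwise `NA` is returned with a warning (the
#' "not equilibrated" signal).
#'
#' @param rg_series numeric matrix (frames x molecules) or vector.
#' @param window window length in frames (default 5% of the series).
#' @return Equilibration frame index (0 = equilibrated from the start), or
#'   `NA` if the series does not plateau early enough.
#' @export
detect_equilibration <- function(rg_series, window = NULL) {
  rg <- as.matrix(rg_series)
  nf <- nrow(rg)
  if (nf < 10) stop("series too short for equilibration detection")
  if (is.null(window)) window <- max(1L, floor(0.05 * nf))
  half <- rg[(floor(nf / 2) + 1):nf, , drop = FALSE]
  mu <- colMeans(half)
  se <- apply(half, 2, sd) / sqrt(window)
  se <- pmax(se, 1e-12 * pmax(abs(mu), 1))
  t_eq <- 0L
  for (m in seq_len(ncol(rg))) {
    ok <- NA
    for (s in seq_len(nf - window + 1L)) {
      wm <- mean(rg[s:(s + window - 1L), m])
      if (abs(wm - mu[m]) <= se[m]) { ok <- s - 1L; break }
    }
    if (is.na(ok)) ok <- nf
    t_eq <- max(t_eq, ok)
  }
  if (t_eq > nf / 8) {
    warning("series not equilibrated (plateau reached too late or never)")
    return(NA_integer_)
  }
  as.integer(t_eq)
}
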