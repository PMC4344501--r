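#' Assemble a condition configuration
#'
#' A condition is one point of the experimental grid: a supercoiling level
#' (linking deficit, `NA` = nicked/torsionally unconstrained) and a volume
#' occupancy, plus simulation scale parameters.  Defaults are desk-scale;
#' the reference study conditions (20 molecules of 334 beads, production
#' sampling every 1000 steps, run length at least eight times the
#' equilibration time) are the `full = TRUE` profile.
#'
#' @param delta_lk linking deficit in turns (`NA` for nicked).
#' @param phi volume occupancy in `[0, 0.3]`.
#' @param n_beads,m_rings system size.
#' @param sampler `"bd"` (Brownian dynamics) or `"mc"` (Monte Carlo).
#' @param n_steps,sample_every BD length and sampling interval.
#' @param n_sweeps,sweep_sample MC length and sampling interval.
#' @param seed RNG seed.
#' @param analyses subset of `c("shape", "topology", "thickness",
#'   "contacts")`.
#' @param ep an [ep_spec()] (required for the `"contacts"` analysis).
#' @param thickness_stride bead stride of the thickness probe.
#' @param pre_relax_sweeps Monte Carlo sweeps used to relax the
#'   constructed starting conformations before Brownian dynamics (the MC
#'   sampler reaches the equilibrium shape basin far faster than BD from
#'   a planar circle or a compact fold); for torsionally constrained
#'   rings the material frames are rebuilt afterwards at the same
#'   linking number.  `0` disables.
#' @param full use the reference-scale profile.
#' @return A `condition_config` list.
#' @export
condition_config <- function(delta_lk = NA, phi = 0, n_beads = 334,
                             m_rings = if (phi > 0) 20 else 5,
                             sampler = c("bd", "mc"),
                             n_steps = 2e5, sample_every = 1000,
                             n_sweeps = 2000, sweep_sample = 10,
                             seed = 1,
                             analyses = c("shape", "topology"),
                             ep = NULL, thickness_stride = 5,
                             pre_relax_sweeps = 2000, full = FALSE) {
  sampler <- match.arg(sampler)
  if (full) {
    n_steps <- 1e7; m_rings <- 20; n_sweeps <- 2e5
  }
  structure(list(delta_lk = delta_lk, phi = phi, n_beads = n_beads,
                 m_rings = m_rings, sampler = sampler, n_steps = n_steps,
                 sample_every = sample_every, n_sweeps = n_sweeps,
                 sweep_sample = sweep_sample, seed = seed,
                 analyses = analyses, ep = ep,
                 thickness_stride = thickness_stride,
                 pre_relax_sweeps = pre_relax_sweeps, full = full),
            class = "condition_config")
}

#' Expand the experimental grid
#'
#' Cross of supercoiling levels and volume occupancies, as in the
#' reference grid of 3 supercoiling levels (nicked, deltaLk = -7, -14)
#' by 4 concentrations (diluted, 5, 10, 20 percent).
#'
#' @param delta_lk vector of linking deficits (`NA` = nicked).
#' @param phi vector of volume occupancies.
#' @param ... passed to [condition_config()].
#' @return List of `condition_config` objects.
#' @examples
#' length(expand_conditions()) # 12
#' @export
expand_conditions <- function(delta_lk = c(NA, -7, -14),
                              phi = c(0, 0.05, 0.10, 0.20), ...) {
  grid <- expand.grid(dlk = delta_lk, phi = phi)
  lapply(seq_len(nrow(grid)), function(i)
    condition_config(delta_lk = grid$dlk[i], phi = grid$phi[i], ...))
}

# short deterministic hash of a config (FNV-1a over its serialization,
# kept in doubles: xor only ever touches the low byte)
config_hash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    lo <- bitwXor(as.integer(h %% 256), b)
    h <- ((h %/% 256) * 256 + lo) * 16777619 %% 4294967296
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run one condition of the experimental grid
#'
#' Initialises the system, equilibrates (monitoring per-molecule radii of
#' gyration; the run must last at least eight times the detected
#' equilibration time), samples, and computes the requested per-frame,
#' per-molecule analysis records.
#'
#' @param config a [condition_config()].
#' @param ff a [force_field()].
#' @return List with `metrics` (the per-frame per-molecule metric table),
#'   `trajectory`, `t_eq` (equilibration frame index), `config`, and
#'   `hash`.
#' @export
run_condition <- function(config, ff = force_field()) {
  stopifnot(inherits(config, "condition_config"))
  set.seed(config$seed)
  topo <- ring_topology(n_beads = config$n_beads,
                        delta_lk = config$delta_lk)
  state <- init_system(topo, m_rings = config$m_rings, phi = config$phi,
                       seed = NA)
  empty <- (config$sampler == "bd" && config$n_steps == 0) ||
           (config$sampler == "mc" && config$n_sweeps == 0)
  if (!empty && config$pre_relax_sweeps > 0) {
    burn <- mc_sample(state, ff, n_sweeps = config$pre_relax_sweeps,
                      sample_every = config$pre_relax_sweeps,
                      delta_lk = config$delta_lk, ep = config$ep,
                      seed = NA)
    state <- burn$final_state
    if (!is.na(config$delta_lk))
      state <- restore_frames(state, config$delta_lk)
  }
  if (config$sampler == "bd") {
    proto <- run_protocol(n_steps = config$n_steps,
                          sample_every = config$sample_every, seed = NA)
    traj <- bd_run(state, ff, proto, ep = config$ep)
  } else {
    traj <- mc_sample(state, ff, n_sweeps = config$n_sweeps,
                      sample_every = config$sweep_sample,
                      delta_lk = config$delta_lk, ep = config$ep,
                      seed = NA)
  }
  t_eq <- 0L
  if (!empty) {
    rg <- trajectory_rg(traj)
    t_eq <- if (nrow(rg) >= 10) detect_equilibration(rg) else 0L
    if (is.na(t_eq))
      stop("condition failed to equilibrate: the run is shorter than ",
           "eight times the detected equilibration time")
  }
  frames <- if (empty) integer(0) else seq(t_eq + 1L, length(traj$frames))
  metrics <- metric_table(traj, frames, topo, config)
  list(metrics = metrics, trajectory = traj, t_eq = t_eq,
       config = config, hash = config_hash(config))
}

# rebuild material frames on a (possibly rewrapped) state at fixed delta_lk
restore_frames <- function(state, delta_lk) {
  up <- unwrap_molecules(state)
  for (r in seq_along(state$rings)) {
    conf <- state$rings[[r]]
    conf$pos <- up[[r]]
    conf <- set_ring_twist(conf, delta_lk)
    wrapped <- wrap_coordinates(list(conf$pos), state$box_length)
    conf$pos <- wrapped$pos[[1]]
    state$image_flags[[r]] <- wrapped$flags[[1]]
    state$rings[[r]] <- conf
  }
  state
}

# per-molecule radius-of-gyration series of a trajectory
trajectory_rg <- function(traj) {
  if (!is.null(traj$rg) && nrow(traj$rg)) return(traj$rg)
  off <- c(0L, cumsum(traj$ring_len))
  t(vapply(traj$frames, function(p)
    vapply(seq_along(traj$ring_len), function(r) {
      q <- p[(off[r] + 1):off[r + 1], , drop = FALSE]
      d <- sweep(q, 2, colMeans(q))
      sqrt(sum(d^2) / nrow(q))
    }, numeric(1)),
    numeric(length(traj$ring_len))))
}

# per-frame, per-molecule analysis records
metric_table <- function(traj, frames, topo, config) {
  cols <- list(frame = integer(), step = integer(), ring_id = integer(),
               rg = numeric())
  if ("shape" %in% config$analyses)
    cols <- c(cols, list(a = numeric(), b = numeric(), c = numeric(),
                         asphericity = numeric(), prolateness = numeric()))
  if ("topology" %in% config$analyses)
    cols <- c(cols, list(tw = numeric(), wr = numeric(), lk = numeric(),
                         sigma = numeric()))
  if ("thickness" %in% config$analyses)
    cols <- c(cols, list(thickness_mean = numeric()))
  if ("contacts" %in% config$analyses)
    cols <- c(cols, list(ep_distance = numeric(), in_contact = logical()))
  out <- list()
  for (f in frames) {
    confs <- trajectory_conformations(traj, f)
    for (r in seq_along(confs)) {
      conf <- confs[[r]]
      d <- sweep(conf$pos, 2, colMeans(conf$pos))
      rec <- list(frame = f, step = traj$steps[f], ring_id = r,
                  rg = sqrt(sum(d^2) / nrow(conf$pos)))
      if ("shape" %in% config$analyses) {
        ax <- inertial_ellipsoid(conf$pos)
        rec <- c(rec, list(a = ax[[1]], b = ax[[2]], c = ax[[3]],
                           asphericity = asphericity(ax),
                           prolateness = prolateness(ax)))
      }
      if ("topology" %in% config$analyses) {
        wr <- writhe(conf$pos)
        tw <- if (!is.null(conf$twist)) twist(conf)
              else if (!is.null(traj$wr)) (config$delta_lk - wr)
              else NA_real_
        lk <- tw + wr
        rec <- c(rec, list(tw = tw, wr = wr, lk = lk,
                           sigma = supercoiling_density(
                             lk, topo$n_bp, topo$helical_repeat)))
      }
      if ("thickness" %in% config$analyses) {
        th <- molecule_thickness(confs, r, box = traj$box,
                                 stride = config$thickness_stride)
        rec <- c(rec, list(thickness_mean = mean(th)))
      }
      if ("contacts" %in% config$analyses) {
        sp <- config$ep
        dd <- sqrt(sum((conf$pos[sp$enhancer_bead, ] -
                        conf$pos[sp$promoter_bead, ])^2))
        rec <- c(rec, list(ep_distance = dd,
                           in_contact = dd < sp$contact_dist))
      }
      out[[length(out) + 1]] <- rec
    }
  }
  if (!length(out))
    return(as.data.frame(cols))
  do.call(rbind, lapply(out, as.data.frame))
}

#' Summarise metric tables per condition
#'
#' Pools one or more per-frame metric tables into per-condition means with
#' standard errors (frames treated as the sampling unit; single-frame
#' tables get `NA` standard errors).
#'
#' @param tables named list of metric tables (or outputs of
#'   [run_condition()]).
#' @return A data.frame with one row per condition.
#' @export
report_conditions <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- paste0("condition_", seq_along(tables))
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    if (is.list(tab) && !is.data.frame(tab) && !is.null(tab$metrics))
      tab <- tab$metrics
    stat <- function(col, abs_val = FALSE) {
      if (!col %in% names(tab) || !nrow(tab))
        return(c(NA_real_, NA_real_))
      v <- tab[[col]]
      if (abs_val) v <- abs(v)
      per_frame <- tapply(v, tab$frame, mean)
      m <- mean(per_frame)
      se <- if (length(per_frame) > 1)
        sd(per_frame) / sqrt(length(per_frame)) else NA_real_
      c(m, se)
    }
    asp <- stat("asphericity"); pro <- stat("prolateness")
    wr <- stat("wr", abs_val = TRUE); th <- stat("thickness_mean")
    ct <- stat("in_contact")
    data.frame(condition = nm, n_records = nrow(tab),
               asphericity = asp[1], asphericity_se = asp[2],
               prolateness = pro[1], prolateness_se = pro[2],
               abs_wr = wr[1], abs_wr_se = wr[2],
               thickness = th[1], thickness_se = th[2],
               contact_fraction = ct[1], contact_fraction_se = ct[2])
  })
  do.call(rbind, rows)
}

#' Read a condition configuration from YAML
#'
#' @param path YAML file with keys matching [condition_config()]
#'   arguments (an `ep:` block is passed to [ep_spec()]).
#' @return A `condition_config`.
#' @export
read_condition_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ep)) y$ep <- do.call(ep_spec, y$ep)
  if (!is.null(y$delta_lk) && identical(y$delta_lk, "nicked"))
    y$delta_lk <- NA
  do.call(condition_config, y)
}
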