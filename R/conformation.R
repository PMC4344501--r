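#' Ring (or chain) conformation
#'
#' One molecule: bead positions, an optional per-edge material frame for
#' torsionally constrained rings, and the per-junction excess-twist angles
#' derived from it.  Positions are in reduced units (sigma_LJ).
#'
#' @param pos numeric n x 3 matrix of bead coordinates.
#' @param frames optional n x 3 matrix of unit material normals, one per
#'   edge (edge i runs from bead i to bead i+1, cyclic); `NULL` for
#'   torsionally unconstrained molecules.
#' @param ring_id identifier.
#' @param closed `TRUE` for circular molecules.
#' @return An object of class `ring_conformation` with elements `pos`,
#'   `frames`, `twist` (per-junction excess-twist angles in radians, or
#'   `NULL`), `ring_id`, `closed`.
#' @seealso [planar_circle()], [twisted_circle()], [set_ring_twist()]
#' @export
ring_conformation <- function(pos, frames = NULL, ring_id = 1L,
                              closed = TRUE) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, nrow(pos) >= (if (closed) 3 else 1))
  storage.mode(pos) <- "double"
  twist <- NULL
  if (!is.null(frames)) {
    frames <- as.matrix(frames)
    stopifnot(nrow(frames) == nrow(pos), ncol(frames) == 3)
    if (!closed) stop("material frames are only supported on closed rings")
    storage.mode(frames) <- "double"
    twist <- cpp_twist_angles(pos, frames)
  }
  structure(list(pos = pos, frames = frames, twist = twist,
                 ring_id = ring_id, closed = closed),
            class = "ring_conformation")
}

#' @export
print.ring_conformation <- function(x, ...) {
  cat(sprintf("<ring_conformation> %d beads, %s%s\n", nrow(x$pos),
              if (x$closed) "closed" else "open",
              if (!is.null(x$twist))
                sprintf(", Tw = %.3f turns", sum(x$twist) / (2 * pi))
              else ", torsionally unconstrained"))
  invisible(x)
}

# parallel-transported (zero-twist) frame field along a closed ring
reference_frames <- function(pos) {
  n <- nrow(pos)
  e <- pos[c(2:n, 1), ] - pos
  u <- e / sqrt(rowSums(e^2))
  m <- matrix(0, n, 3)
  # seed normal perpendicular to the first tangent
  seed <- if (abs(u[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  m0 <- seed - sum(seed * u[1, ]) * u[1, ]
  m[1, ] <- m0 / sqrt(sum(m0^2))
  for (i in seq_len(n - 1)) {
    a <- u[i, ]; b <- u[i + 1, ]
    ax <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    s <- sqrt(sum(ax^2)); cc <- sum(a * b)
    if (s < 1e-14) {
      m[i + 1, ] <- m[i, ]
    } else {
      ax <- ax / s
      th <- atan2(s, cc)
      v <- m[i, ]
      m[i + 1, ] <- v * cos(th) + c(ax[2] * v[3] - ax[3] * v[2],
                                    ax[3] * v[1] - ax[1] * v[3],
                                    ax[1] * v[2] - ax[2] * v[1]) * sin(th) +
        ax * sum(ax * v) * (1 - cos(th))
    }
    # keep exactly perpendicular to the tangent
    m[i + 1, ] <- m[i + 1, ] - sum(m[i + 1, ] * b) * b
    m[i + 1, ] <- m[i + 1, ] / sqrt(sum(m[i + 1, ]^2))
  }
  m
}

#' Impose a target linking deficit on a closed ring
#'
#' Builds (or rebuilds) the material frame field of a ring so that its
#' linking number Lk = Tw + Wr equals `delta_lk` turns.  Starting from the
#' parallel-transported (twist-free) frame field, an integer number of
#' uniform frame rotations is wound along the ring; the linking number of a
#' closed ribbon being an integer invariant, `delta_lk` must be integer.
#'
#' @param conf a closed [ring_conformation()].
#' @param delta_lk target linking deficit (integer turns).
#' @return The conformation with `frames` and `twist` set such that
#'   `sum(twist)/(2*pi) + writhe(conf) == delta_lk` up to numerical
#'   round-off.
#' @examples
#' conf <- set_ring_twist(planar_circle(100), -7)
#' sum(conf$twist) / (2 * pi) # -7: planar ring, all deficit in twist
#' @export
set_ring_twist <- function(conf, delta_lk) {
  stopifnot(inherits(conf, "ring_conformation"), conf$closed)
  if (delta_lk != round(delta_lk))
    stop("delta_lk must be an integer number of turns")
  pos <- conf$pos
  n <- nrow(pos)
  m <- reference_frames(pos)
  tw0 <- sum(cpp_twist_angles(pos, m)) / (2 * pi)
  wr0 <- cpp_writhe(pos)
  lk0 <- round(tw0 + wr0)
  add <- delta_lk - lk0
  if (add != 0) {
    e <- pos[c(2:n, 1), ] - pos
    u <- e / sqrt(rowSums(e^2))
    psi <- (seq_len(n) - 1) * 2 * pi * add / n
    cs <- cos(psi); sn <- sin(psi)
    kxv <- cbind(u[, 2] * m[, 3] - u[, 3] * m[, 2],
                 u[, 3] * m[, 1] - u[, 1] * m[, 3],
                 u[, 1] * m[, 2] - u[, 2] * m[, 1])
    kdv <- rowSums(u * m)
    m <- m * cs + kxv * sn + u * (kdv * (1 - cs))
  }
  conf$frames <- m
  conf$twist <- cpp_twist_angles(pos, m)
  conf
}

#' Multi-molecule system state
#'
#' A set of molecules in a (possibly periodic) cubic box.  Coordinates held
#' in the `rings` list are wrapped into `[0, box_length)` when the box is
#' finite; `image_flags` record the periodic wraps so molecules can be
#' reconstructed exactly with [unwrap_molecules()].  A non-finite
#' `box_length` denotes dilute, non-interacting molecules.
#'
#' @param rings list of [ring_conformation()] objects (wrapped coordinates).
#' @param box_length cubic box edge in sigma_LJ, or `Inf` for dilute.
#' @param image_flags list of integer n x 3 matrices, one per ring.
#' @param step integer simulation step the state corresponds to.
#' @return An object of class `system_state`.
#' @export
system_state <- function(rings, box_length = Inf, image_flags = NULL,
                         step = 0L) {
  stopifnot(is.list(rings), length(rings) >= 1)
  if (is.null(image_flags))
    image_flags <- lapply(rings, function(r) {
      matrix(0L, nrow(r$pos), 3)
    })
  stopifnot(length(image_flags) == length(rings))
  structure(list(rings = rings, box_length = box_length,
                 image_flags = image_flags, step = as.integer(step)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d molecules x %d beads, box %s, phi = %.3f\n",
              length(x$rings), nrow(x$rings[[1]]$pos),
              if (is.finite(x$box_length))
                sprintf("%.2f sigma", x$box_length) else "none (dilute)",
              volume_fraction(x)))
  invisible(x)
}

#' Bead volume fraction of a system
#'
#' Fraction of the periodic box volume occupied by bead spheres of diameter
#' 1 sigma: `phi = N * (pi/6) / L^3`.  Zero for dilute (infinite box)
#' systems.
#'
#' @param state a [system_state()].
#' @return Volume fraction in `[0, 1]`.
#' @export
volume_fraction <- function(state) {
  if (!is.finite(state$box_length)) return(0)
  n <- sum(vapply(state$rings, function(r) nrow(r$pos), integer(1)))
  n * (pi / 6) / state$box_length^3
}

#' Reconstruct contiguous molecules across periodic boundaries
#'
#' Shifts each molecule's wrapped coordinates by `box_length * image_flags`
#' so that every bond is short and the molecule is contiguous in space.
#' Shape, writhe and thickness analyses always consume unwrapped
#' coordinates.
#'
#' @param state a [system_state()].
#' @return List of n x 3 coordinate matrices, one per molecule.
#' @export
unwrap_molecules <- function(state) {
  L <- state$box_length
  out <- lapply(seq_along(state$rings), function(i) {
    p <- state$rings[[i]]$pos
    if (is.finite(L)) p <- p + L * state$image_flags[[i]]
    p
  })
  if (is.finite(L)) {
    for (i in seq_along(out)) {
      p <- out[[i]]
      n <- nrow(p)
      if (n < 2) next
      e <- p[c(2:n, 1), ] - p
      bl <- sqrt(rowSums(e^2))
      nb <- if (state$rings[[i]]$closed) n else n - 1
      if (any(bl[seq_len(nb)] > 2))
        stop("corrupted image flags: bond longer than 2 sigma after unwrap")
    }
  }
  out
}

#' Wrap unwrapped molecule coordinates into the periodic box
#'
#' Inverse of [unwrap_molecules()]: computes image flags
#' `floor(pos / box_length)` and wrapped coordinates in `[0, box_length)`.
#'
#' @param pos_list list of unwrapped n x 3 coordinate matrices.
#' @param box_length cubic box edge (may be `Inf`, in which case
#'   coordinates pass through with zero flags).
#' @return List with elements `pos` (wrapped matrices) and `flags`
#'   (integer matrices).
#' @export
wrap_coordinates <- function(pos_list, box_length) {
  flags <- lapply(pos_list, function(p) {
    if (!is.finite(box_length)) return(matrix(0L, nrow(p), 3))
    f <- floor(p / box_length)
    storage.mode(f) <- "integer"
    f
  })
  pos <- Map(function(p, f) {
    if (!is.finite(box_length)) return(p)
    p - box_length * f
  }, pos_list, flags)
  list(pos = pos, flags = flags)
}
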