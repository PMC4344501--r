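#' Trajectory container
#'
#' Ordered snapshots of a multi-molecule system: unwrapped coordinates (one
#' stacked matrix per frame), per-junction twist angles for torsionally
#' constrained rings, per-frame radii of gyration and energy components,
#' plus the metadata needed to replay the run.
#'
#' @param frames list of N x 3 unwrapped coordinate matrices.
#' @param twist list of length-N twist-angle vectors (or `NULL`).
#' @param ring_len integer vector of beads per molecule.
#' @param closed,torsion logical vectors per molecule.
#' @param box cubic box edge (`Inf` for dilute).
#' @param steps integer step index of each frame.
#' @param rg frames x molecules matrix of radii of gyration.
#' @param energy frames x components energy matrix.
#' @param metadata list (force field, protocol, seed, ...).
#' @return An object of class `sc_trajectory`.
#' @export
sc_trajectory <- function(frames, twist = NULL, ring_len, closed, torsion,
                          box = Inf, steps = seq_along(frames),
                          rg = NULL, energy = NULL, metadata = list()) {
  structure(list(frames = frames, twist = twist,
                 ring_len = as.integer(ring_len),
                 closed = closed, torsion = torsion, box = box,
                 steps = as.integer(steps), rg = rg, energy = energy,
                 metadata = metadata),
            class = "sc_trajectory")
}

#' @export
print.sc_trajectory <- function(x, ...) {
  cat(sprintf("<sc_trajectory> %d frames, %d molecules, box %s\n",
              length(x$frames), length(x$ring_len),
              if (is.finite(x$box)) sprintf("%.2f", x$box) else "none"))
  invisible(x)
}

#' Extract molecule conformations from one trajectory frame
#'
#' @param traj an `sc_trajectory`.
#' @param frame frame index.
#' @return List of [ring_conformation()] objects (unwrapped coordinates;
#'   twist angles attached where the molecule is torsionally constrained).
#' @export
trajectory_conformations <- function(traj, frame) {
  p <- traj$frames[[frame]]
  off <- c(0L, cumsum(traj$ring_len))
  lapply(seq_along(traj$ring_len), function(r) {
    idx <- (off[r] + 1):off[r + 1]
    tw <- if (!is.null(traj$twist) && length(traj$twist) >= frame &&
              !is.null(traj$twist[[frame]]) && traj$torsion[r])
      traj$twist[[frame]][idx]
    structure(list(pos = p[idx, , drop = FALSE], frames = NULL,
                   twist = tw, ring_id = r, closed = traj$closed[r]),
              class = "ring_conformation")
  })
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: the bead count, a comment line carrying the cubic
#' lattice, the step index and the column layout, then one line per bead
#' with wrapped coordinates, molecule id, the three periodic image flags
#' and the per-junction excess-twist angle (0 for unconstrained
#' molecules).  Metadata (force field, protocol) travels in a YAML sidecar
#' header so that `read_xyz()` can replay the file losslessly.
#'
#' @param traj an `sc_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  n <- sum(traj$ring_len)
  ring_id <- rep(seq_along(traj$ring_len), traj$ring_len)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(ring_len = as.integer(traj$ring_len),
               closed = as.logical(traj$closed),
               torsion = as.logical(traj$torsion),
               box = if (is.finite(traj$box)) traj$box else 0)
  writeLines("# supercoilr extended-xyz", con)
  writeLines(paste0("#| ",
                    strsplit(yaml::as.yaml(meta, precision = 15),
                             "\n")[[1]]), con)
  L <- traj$box
  for (k in seq_along(traj$frames)) {
    p <- traj$frames[[k]]
    if (is.finite(L)) {
      flags <- floor(p / L)
      w <- p - L * flags
    } else {
      flags <- matrix(0, n, 3)
      w <- p
    }
    tw <- if (!is.null(traj$twist) && !is.null(traj$twist[[k]]))
      traj$twist[[k]] else rep(0, n)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:ring_id:I:1:image:I:3:twist:R:1 step=%d',
      if (is.finite(L)) L else 0, if (is.finite(L)) L else 0,
      if (is.finite(L)) L else 0, traj$steps[k]), con)
    writeLines(sprintf("C %.17g %.17g %.17g %d %d %d %d %.17g",
                       w[, 1], w[, 2], w[, 3], ring_id,
                       flags[, 1], flags[, 2], flags[, 3], tw), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_xyz()]: reconstructs unwrapped coordinates from the
#' wrapped ones and the image flags.  Malformed or truncated files raise an
#' error naming the offending frame.
#'
#' @param path file written by [write_xyz()].
#' @return An `sc_trajectory`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# supercoilr"))
    stop("not a supercoilr extended-XYZ file")
  nhead <- 1L
  while (nhead < length(lines) && startsWith(lines[nhead + 1L], "#| "))
    nhead <- nhead + 1L
  meta <- yaml::yaml.load(
    paste(sub("^#\\| ", "", lines[2:nhead]), collapse = "\n"))
  box <- if (meta$box > 0) meta$box else Inf
  n <- sum(meta$ring_len)
  i <- nhead + 1L
  frames <- list()
  twist <- list()
  steps <- integer()
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    nn <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nn) || nn != n)
      stop(sprintf("malformed frame %d: bad bead count line", fidx))
    if (i + 1L + nn > length(lines))
      stop(sprintf("truncated file within frame %d", fidx))
    step <- suppressWarnings(
      as.integer(sub(".*step=([0-9-]+).*", "\\1", lines[i + 1L])))
    body <- lines[(i + 2L):(i + 1L + nn)]
    dt <- data.table::fread(text = body, header = FALSE)
    if (ncol(dt) != 9)
      stop(sprintf("malformed frame %d: expected 9 columns", fidx))
    w <- as.matrix(dt[, 2:4])
    flags <- as.matrix(dt[, 6:8])
    p <- if (is.finite(box)) w + box * flags else w
    dimnames(p) <- NULL
    frames[[fidx]] <- p
    twist[[fidx]] <- dt[[9]]
    steps[fidx] <- if (is.na(step)) fidx else step
    i <- i + 2L + nn
  }
  sc_trajectory(frames, twist = twist, ring_len = meta$ring_len,
                closed = meta$closed, torsion = meta$torsion,
                box = box, steps = steps)
}
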