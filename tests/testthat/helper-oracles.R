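# Independent oracles used across the suite.  These deliberately avoid the
# package's computational kernels: writhe by brute-force quadrature of the
# Gauss integral, thickness by the per-azimuth geometric bound, bending by
# an angle-by-angle R sum.

# Dense midpoint quadrature of the Gauss writhe integral,
#   Wr = (1/4pi) sum_ij (dr_i x dr_j) . (r_i - r_j) / |r_i - r_j|^3,
# with k points per segment; adjacent segment pairs skipped as in the
# closed form.
gauss_writhe_oracle <- function(pos, k = 200) {
  n <- nrow(pos)
  nodes <- (seq_len(k) - 0.5) / k
  segs <- lapply(seq_len(n), function(i) {
    a <- pos[i, ]
    b <- pos[(i %% n) + 1, ]
    list(p = outer(rep(1, k), a) + outer(nodes, b - a), d = (b - a) / k)
  })
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sep <- abs(i - j)
    if (sep <= 1 || sep == n - 1) next
    di <- segs[[i]]$d
    dj <- segs[[j]]$d
    cx <- c(di[2] * dj[3] - di[3] * dj[2],
            di[3] * dj[1] - di[1] * dj[3],
            di[1] * dj[2] - di[2] * dj[1])
    Pi <- segs[[i]]$p
    Pj <- segs[[j]]$p
    for (a in seq_len(k)) {
      r <- outer(rep(1, k), Pi[a, ]) - Pj      # r_i - r_j
      rn2 <- rowSums(r^2)
      total <- total + sum((r %*% cx) / (rn2 * sqrt(rn2)))
    }
  }
  total / (4 * pi)
}

# Geometric per-azimuth bound for the tangent-sphere probe: the largest
# centre offset s = rho + 1/2 along direction u that keeps every obstacle
# at |s u - d| >= s is  min over {j : u.d_j > 0} of |d_j|^2 / (2 u.d_j).
# Derived by expanding |s u - d|^2 >= s^2; independent of the bisection.
thickness_oracle <- function(confs, ring = 1, bead, excl = 10, n_az = 36,
                             max_radius = 15) {
  if (inherits(confs, "ring_conformation")) confs <- list(confs)
  lens <- vapply(confs, function(x) nrow(x$pos), integer(1))
  off <- c(0L, cumsum(lens))
  allpos <- do.call(rbind, lapply(confs, `[[`, "pos"))
  me <- off[ring] + bead
  nc <- lens[ring]
  closed <- confs[[ring]]$closed
  vp <- if (closed) (bead - 2) %% nc + 1 else bead - 1
  vn <- if (closed) bead %% nc + 1 else bead + 1
  t <- allpos[off[ring] + vn, ] - allpos[off[ring] + vp, ]
  t <- t / sqrt(sum(t^2))
  keep <- rep(TRUE, nrow(allpos))
  sep <- abs(seq_len(nc) - bead)
  if (closed) sep <- pmin(sep, nc - sep)
  keep[off[ring] + which(sep <= excl)] <- FALSE
  d <- sweep(allpos[keep, , drop = FALSE], 2, allpos[me, ])
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * t) * t
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t[2] * e1[3] - t[3] * e1[2],
          t[3] * e1[1] - t[1] * e1[3],
          t[1] * e1[2] - t[2] * e1[1])
  smax <- max_radius + 0.5
  rho <- max_radius
  for (a in 2 * pi * (seq_len(n_az) - 1) / n_az) {
    u <- cos(a) * e1 + sin(a) * e2
    ud <- d %*% u
    pos_side <- ud > 0
    s <- if (any(pos_side))
      min(rowSums(d[pos_side, , drop = FALSE]^2) / (2 * ud[pos_side]))
    else Inf
    rho <- min(rho, min(s, smax) - 0.5)
  }
  2 * max(rho, 0) + 1
}

# angle-by-angle bending energy of one chain (independent of the kernel)
bend_oracle <- function(pos, kappa = 17, closed = TRUE) {
  n <- nrow(pos)
  idx <- if (closed) seq_len(n) else 2:(n - 1)
  total <- 0
  for (i in idx) {
    ip <- if (i == 1) n else i - 1
    inx <- if (i == n) 1 else i + 1
    e1 <- pos[i, ] - pos[ip, ]
    e2 <- pos[inx, ] - pos[i, ]
    ct <- sum(e1 * e2) / sqrt(sum(e1^2) * sum(e2^2))
    total <- total + kappa * (1 - ct)
  }
  total
}

# pooled tangent-tangent correlation over a list of chain coordinate
# matrices, up to arc separation smax
tangent_correlation <- function(frames, smax = 30) {
  acc <- numeric(smax)
  cnt <- numeric(smax)
  for (p in frames) {
    e <- diff(p)
    e <- e / sqrt(rowSums(e^2))
    ne <- nrow(e)
    for (s in seq_len(smax)) {
      acc[s] <- acc[s] +
        sum(rowSums(e[1:(ne - s), , drop = FALSE] *
                    e[(1 + s):ne, , drop = FALSE]))
      cnt[s] <- cnt[s] + ne - s
    }
  }
  acc / cnt
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
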