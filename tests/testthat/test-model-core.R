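test_that("repulsive energy matches the truncated-LJ closed form", {
  two_beads <- function(r)
    list(ring_conformation(matrix(c(0, 0, 0), 1, 3), closed = FALSE),
         ring_conformation(matrix(c(r, 0, 0), 1, 3), closed = FALSE))
  expect_equal(as.numeric(energy_repulsive(two_beads(1.0))), 0)
  expect_equal(as.numeric(energy_repulsive(two_beads(1.5))), 0)
  expect_equal(as.numeric(energy_repulsive(two_beads(0.9))),
               4 * (0.9^-12 - 0.9^-6), tolerance = 1e-12)
  # continuous at the cutoff: the LJ form vanishes at r = sigma
  expect_lt(abs(energy_repulsive(two_beads(1 - 1e-8))), 1e-6)
  expect_lt(abs(energy_repulsive(two_beads(1 - 1e-10))), 1e-8)
  # bonded neighbours are excluded
  dimer <- list(ring_conformation(rbind(c(0, 0, 0), c(0.9, 0, 0)),
                                  closed = FALSE))
  expect_equal(as.numeric(energy_repulsive(dimer)), 0)
  # overlap guard flags the capped energy
  expect_true(attr(energy_repulsive(two_beads(1e-6)), "capped"))
})

test_that("bending energy is kappa(1 - cos) summed over junctions", {
  straight <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(energy_bend(straight, closed = FALSE), 0)
  right <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(energy_bend(right, closed = FALSE), 17)
  ngon <- planar_circle(334)
  expect_equal(energy_bend(ngon), 334 * 17 * (1 - cos(2 * pi / 334)),
               tolerance = 1e-10)
  degenerate <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(energy_bend(degenerate, closed = FALSE), "zero-length")
})

test_that("bending energy of planar polygons equals the angle-by-angle sum", {
  set.seed(17)
  for (n in c(8, 21, 55)) {
    th <- sort(runif(n, 0, 2 * pi))           # random planar convex polygon
    pos <- cbind(3 * cos(th), 3 * sin(th), 0)
    expect_equal(energy_bend(pos), bend_oracle(pos), tolerance = 1e-12)
  }
  # and a non-planar random walk, open
  p <- equilibrium_chain(30, seed = 5)$pos
  expect_equal(energy_bend(p, closed = FALSE),
               bend_oracle(p, closed = FALSE), tolerance = 1e-12)
})

test_that("bond energy is harmonic and symmetric about the rest length", {
  flat <- planar_circle(64)
  expect_equal(energy_bond(flat), 0, tolerance = 1e-20)
  one <- rbind(c(0, 0, 0), c(1.1, 0, 0))
  expect_equal(energy_bond(one, closed = FALSE), 0.5 * 800 * 0.1^2)
  short <- rbind(c(0, 0, 0), c(0.9, 0, 0))
  expect_equal(energy_bond(one, closed = FALSE),
               energy_bond(short, closed = FALSE))
})

test_that("twist energy is harmonic in the junction angles", {
  relaxed <- twisted_circle(100, 0)
  expect_equal(energy_twist(relaxed), 0, tolerance = 1e-16)
  ff <- force_field()
  t7 <- twisted_circle(334, -7)
  expect_equal(energy_twist(t7),
               334 * 0.5 * ff$k_twist * (2 * pi * 7 / 334)^2,
               tolerance = 1e-9)
  # doubling all angles (deltaLk -7 -> -14) quadruples the energy
  t14 <- twisted_circle(334, -14)
  expect_equal(energy_twist(t14) / energy_twist(t7), 4, tolerance = 1e-9)
  nicked <- planar_circle(64)
  expect_error(energy_twist(nicked), "twist")
})

test_that("persistence length follows the worm-like-chain closed form", {
  expect_equal(persistence_length(17, bond = 3), 49.48, tolerance = 1e-3)
  expect_equal(persistence_length(17, bond = 1), 16.49, tolerance = 1e-3)
  # stiff-rod limit L_p -> kappa * b
  expect_equal(persistence_length(1000, bond = 1) / 1000, 1,
               tolerance = 5e-3)
  expect_error(persistence_length(0), "positive")
  expect_error(persistence_length(-3), "positive")
})

test_that("all energy terms are invariant under rigid motions", {
  set.seed(4)
  conf <- twisted_circle(64, -3)
  conf$pos <- conf$pos + 0.02 * matrix(rnorm(64 * 3), 64, 3)
  conf$twist <- supercoilr:::cpp_twist_angles(conf$pos, conf$frames)
  R <- random_rotation()
  shift <- c(5, -2, 11)
  rot <- conf
  rot$pos <- sweep(conf$pos %*% t(R), 2, shift, "+")
  rot$frames <- conf$frames %*% t(R)
  rot$twist <- supercoilr:::cpp_twist_angles(rot$pos, rot$frames)
  for (f in list(energy_bend, energy_bond)) {
    e0 <- f(conf$pos)
    expect_equal(f(rot$pos), e0, tolerance = 1e-10)
  }
  expect_equal(as.numeric(energy_repulsive(list(rot))),
               as.numeric(energy_repulsive(list(conf))), tolerance = 1e-10)
  expect_equal(energy_twist(rot), energy_twist(conf), tolerance = 1e-8)
})

test_that("analytic forces agree with finite differences of the energy", {
  # transports each edge frame alongside the perturbation, exactly as the
  # dynamics does, so the twist gradient check includes the holonomy term
  transport_frames <- function(pos_old, pos_new, m) {
    n <- nrow(pos_old)
    uo <- pos_old[c(2:n, 1), ] - pos_old
    uo <- uo / sqrt(rowSums(uo^2))
    un <- pos_new[c(2:n, 1), ] - pos_new
    un <- un / sqrt(rowSums(un^2))
    for (i in seq_len(n)) {
      a <- uo[i, ]; b <- un[i, ]
      ax <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      s <- sqrt(sum(ax^2)); cc <- sum(a * b)
      if (s > 1e-14) {
        ax <- ax / s; th <- atan2(s, cc); v <- m[i, ]
        m[i, ] <- v * cos(th) +
          c(ax[2] * v[3] - ax[3] * v[2], ax[3] * v[1] - ax[1] * v[3],
            ax[1] * v[2] - ax[2] * v[1]) * sin(th) +
          ax * sum(ax * v) * (1 - cos(th))
      }
      m[i, ] <- m[i, ] - sum(m[i, ] * un[i, ]) * un[i, ]
      m[i, ] <- m[i, ] / sqrt(sum(m[i, ]^2))
    }
    m
  }
  set.seed(1)
  conf <- twisted_circle(40, -3)
  pos <- conf$pos + 0.05 * matrix(rnorm(120), 40, 3)
  m <- transport_frames(conf$pos, pos, conf$frames)
  kt <- 31.7
  res <- supercoilr:::cpp_chain_forces(pos, m, TRUE, -1, 800, 1, 17, kt,
                                       TRUE, TRUE, 1, 1)
  energy_at <- function(p, mm) {
    supercoilr:::cpp_energy_bond(p, TRUE, 800, 1) +
      supercoilr:::cpp_energy_bend(p, TRUE, 17) +
      sum(0.5 * kt * supercoilr:::cpp_twist_angles(p, mm)^2) +
      supercoilr:::cpp_energy_repulsive(p, -1, 40L, TRUE, 1, 1)$energy
  }
  h <- 1e-6
  for (i in c(1, 13, 40)) for (d in 1:3) {
    pp <- pos; pp[i, d] <- pp[i, d] + h
    pm <- pos; pm[i, d] <- pm[i, d] - h
    fd <- -(energy_at(pp, transport_frames(pos, pp, m)) -
            energy_at(pm, transport_frames(pos, pm, m))) / (2 * h)
    expect_equal(res$forces[i, d], fd, tolerance = 1e-5)
  }
  # forces sum to zero (translation invariance)
  expect_lt(max(abs(colSums(res$forces))), 1e-9)
})
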