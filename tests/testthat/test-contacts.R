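test_that("enhancer-promoter potential is a shifted truncated LJ well", {
  sp <- ep_spec()
  expect_equal(ep_energy(2.0, sp), 0)
  expect_equal(ep_energy(2.5, sp), 0)
  shift <- 4 * 8 * (2^-12 - 2^-6)
  expect_equal(ep_energy(2^(1 / 6), sp), -8 - shift, tolerance = 1e-12)
  # continuous at the cutoff
  expect_lt(abs(ep_energy(2 - 1e-9, sp)), 1e-6)
  expect_true(all(diff(ep_energy(seq(2^(1 / 6), 1.99, 0.01), sp)) > 0))
})

test_that("contact fraction recovers constructed dwell statistics", {
  # two-state synthetic trajectory with known 25% contact occupancy
  frames <- lapply(1:200, function(k) {
    d <- if (k %% 4 == 0) 1.5 else 3
    rbind(c(0, 0, 0), c(d, 0, 0))
  })
  traj <- sc_trajectory(frames, ring_len = 2, closed = FALSE,
                        torsion = FALSE)
  sp <- ep_spec(enhancer_bead = 1, promoter_bead = 2)
  cf <- contact_fraction(traj, sp)
  expect_equal(cf$fraction, 0.25, tolerance = 1e-12)
  expect_true(is.finite(cf$se))
  # permanently bound and permanently free
  bound <- sc_trajectory(rep(list(rbind(c(0, 0, 0), c(1.1, 0, 0))), 20),
                         ring_len = 2, closed = FALSE, torsion = FALSE)
  expect_equal(contact_fraction(bound, sp)$fraction, 1)
  free <- sc_trajectory(rep(list(rbind(c(0, 0, 0), c(3, 0, 0))), 20),
                        ring_len = 2, closed = FALSE, torsion = FALSE)
  expect_equal(contact_fraction(free, sp)$fraction, 0)
})

test_that("linear control preserves separation and affinity but not closure", {
  lc <- make_linear_control(ep_spec(), n_beads = 334)
  expect_false(lc$conf$closed)
  expect_equal(nrow(lc$conf$pos), 334)
  # n - 1 bonds of length 1, no closure bond
  bl <- sqrt(rowSums(diff(lc$conf$pos)^2))
  expect_equal(length(bl), 333)
  expect_true(all(abs(bl - 1) < 1e-12))
  expect_equal(lc$spec$promoter_bead - lc$spec$enhancer_bead, 167)
  expect_null(lc$conf$twist)
})
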