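test_that("touching strands give a thickness of one bead diameter", {
  s <- parallel_strands(d = 1, length = 21)
  expect_equal(local_thickness(s, ring = 1, bead = 11), 1, tolerance = 1e-9)
  # strands two diameters apart: probe radius 1/2, thickness 2
  s2 <- parallel_strands(d = 2, length = 21)
  expect_equal(local_thickness(s2, ring = 1, bead = 11), 2, tolerance = 2e-3)
})

test_that("an unobstructed rod caps at the maximum probe radius", {
  rod <- ring_conformation(cbind(0, 0, 1:21), closed = FALSE)
  p <- thickness_params()
  expect_equal(local_thickness(rod, bead = 11), 2 * p$max_radius + 1)
  expect_error(local_thickness(rod, bead = 1), "endpoint")
  expect_error(local_thickness(rod, bead = 21), "endpoint")
})

test_that("bisection agrees with the geometric per-azimuth oracle", {
  for (d in c(1.5, 2, 3.2, 4)) {
    s <- parallel_strands(d, length = 25)
    expect_equal(local_thickness(s, ring = 1, bead = 13),
                 thickness_oracle(s, ring = 1, bead = 13), tolerance = 2e-3)
  }
  # curved obstruction: a ring probed against itself
  set.seed(9)
  conf <- plectoneme(120, 3)
  for (b in c(10, 40, 77)) {
    expect_equal(local_thickness(conf, bead = b),
                 thickness_oracle(conf, bead = b), tolerance = 2e-3)
  }
})

test_that("thickness is bounded below and monotone in the obstruction set", {
  set.seed(14)
  conf <- plectoneme(120, 3)
  vals <- molecule_thickness(conf, stride = 7)
  expect_true(all(vals >= 1))
  # adding another molecule can only decrease or preserve the thickness
  blocker <- ring_conformation(conf$pos + c(2, 0, 0), ring_id = 2L)
  both <- list(conf, blocker)
  for (b in c(15, 60)) {
    expect_lte(local_thickness(both, ring = 1, bead = b),
               local_thickness(conf, bead = b) + 1e-12)
  }
  # exclusion flag: other molecules ignored on request
  p_excl <- thickness_params(include_other_rings = FALSE)
  expect_equal(local_thickness(both, ring = 1, bead = 15, params = p_excl),
               local_thickness(conf, bead = 15), tolerance = 1e-12)
})

test_that("plectoneme thickness mode sits at the interwound spacing", {
  conf <- plectoneme(200, 5, superhelix_radius = 1.5, pitch = 6)
  th <- thickness_ensemble(
    sc_trajectory(list(conf$pos), ring_len = nrow(conf$pos), closed = TRUE,
                  torsion = FALSE),
    params = thickness_params(), stride = 2)
  # two helices at superhelix radius 1.5: centre-centre spacing ~3 sigma
  expect_lt(th$mode, 4.5)
  expect_gt(th$mode, 1.5)
  widths <- diff(th$profile$bin_center)[1]
  expect_equal(sum(th$profile$density) * widths, 1, tolerance = 1e-9)
})
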