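test_that("planar circle is a regular, writhe-free, oblate ring", {
  for (n in c(3, 64, 334)) {
    conf <- planar_circle(n)
    expect_equal(writhe(conf), 0)
    bl <- sqrt(rowSums((conf$pos[c(2:n, 1), ] - conf$pos)^2))
    expect_equal(max(bl) - min(bl), 0, tolerance = 1e-12)
    expect_equal(mean(bl), 1, tolerance = 1e-12)
  }
  # oblate-disc limit of the asphericity formula: a = b, c -> 0 gives 1/4
  expect_equal(asphericity(inertial_ellipsoid(planar_circle(334)$pos)),
               0.25, tolerance = 1e-4)
})

test_that("twisted circle puts the whole linking deficit into twist", {
  for (dlk in c(0, -7, -14)) {
    conf <- twisted_circle(334, dlk)
    expect_equal(twist(conf), dlk, tolerance = 1e-9)
    expect_equal(writhe(conf), 0)
    expect_equal(twist(conf) + writhe(conf), dlk, tolerance = 1e-9)
  }
  ff <- force_field()
  expect_equal(energy_twist(twisted_circle(334, -7), ff),
               334 * 0.5 * ff$k_twist * (2 * pi * 7 / 334)^2,
               tolerance = 1e-9)
})

test_that("plectoneme has the constructed writhe, sign flipping with handedness", {
  pl <- plectoneme(200, 5)
  expect_lt(abs(writhe(pl) - (-5)) / 5, 0.10)
  expect_equal(writhe(plectoneme(200, 5, handedness = -1)), -writhe(pl),
               tolerance = 1e-10)
  # small instance against the dense quadrature oracle
  small <- plectoneme(60, 2, superhelix_radius = 1.5, pitch = 7)
  expect_equal(writhe(small), gauss_writhe_oracle(small$pos, k = 60),
               tolerance = 1e-2)
  # self-intersecting parameters rejected
  expect_error(plectoneme(40, 8, superhelix_radius = 1.5, pitch = 3),
               "beads|intersect")
})

test_that("ellipsoid shell fixture round-trips through the moment solver", {
  sph <- inertial_ellipsoid(ellipsoid_shell(2, 2, 2, 10000, seed = 2))
  expect_true(all(abs(sph / 2 - 1) < 0.02))
  ax <- inertial_ellipsoid(ellipsoid_shell(4, 2, 1, 10000, seed = 1))
  expect_true(all(abs(ax / c(4, 2, 1) - 1) < 0.03))
  expect_equal(asphericity(ax), asphericity(c(4, 2, 1)), tolerance = 0.03)
  expect_equal(prolateness(ax), prolateness(c(4, 2, 1)), tolerance = 0.05)
  # bitwise deterministic under a fixed seed
  expect_identical(ellipsoid_shell(4, 2, 1, 100, seed = 9),
                   ellipsoid_shell(4, 2, 1, 100, seed = 9))
})

test_that("parallel strands realise the close-apposition geometry", {
  s <- parallel_strands(d = 1, length = 21)
  expect_equal(nrow(s[[1]]$pos), 21)
  expect_false(s[[1]]$closed)
  expect_equal(sqrt(sum((s[[1]]$pos[5, ] - s[[2]]$pos[5, ])^2)), 1)
  expect_error(parallel_strands(d = 0.5), "d")
})

test_that("equilibrium chain samples the ideal-chain Boltzmann statistics", {
  set.seed(8)
  chains <- replicate(300, equilibrium_chain(100)$pos, simplify = FALSE)
  cc <- tangent_correlation(chains, smax = 10)
  theory <- (1 / tanh(17) - 1 / 17)^(1:10)
  expect_true(all(abs(cc - theory) < 0.01))
  bl <- unlist(lapply(chains, function(p) sqrt(rowSums(diff(p)^2))))
  expect_equal(mean(bl), 1, tolerance = 0.01)
  expect_equal(sd(bl), sqrt(1 / 800), tolerance = 0.1)
  expect_identical(equilibrium_chain(50, seed = 3)$pos,
                   equilibrium_chain(50, seed = 3)$pos)
})
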