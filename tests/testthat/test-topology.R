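test_that("writhe closed form matches dense Gauss quadrature", {
  set.seed(3)
  n <- 32
  th <- 2 * pi * (0:(n - 1)) / n
  wavy <- cbind(cos(th) + 0.3 * cos(2 * th), sin(th) + 0.3 * sin(2 * th),
                0.4 * sin(3 * th))
  expect_equal(writhe(wavy), gauss_writhe_oracle(wavy, k = 200),
               tolerance = 1e-3)
  trefoil <- cbind((2 + cos(3 * th)) * cos(2 * th),
                   (2 + cos(3 * th)) * sin(2 * th), sin(3 * th))
  expect_equal(writhe(trefoil), gauss_writhe_oracle(trefoil, k = 100),
               tolerance = 1e-3)
  pl <- plectoneme(60, 2)$pos
  expect_equal(writhe(pl), gauss_writhe_oracle(pl, k = 100),
               tolerance = 1e-3)
})

test_that("writhe is a rigid-motion and scale invariant chirality measure", {
  set.seed(11)
  pos <- plectoneme(80, 3)$pos
  w0 <- writhe(pos)
  R <- random_rotation()
  expect_equal(writhe(sweep(pos %*% t(R), 2, c(3, -1, 7), "+")), w0,
               tolerance = 1e-10)
  expect_equal(writhe(pos * 17.3), w0, tolerance = 1e-10)
  mirror <- pos
  mirror[, 3] <- -mirror[, 3]
  expect_equal(writhe(mirror), -w0, tolerance = 1e-10)
  expect_equal(writhe(planar_circle(3)), 0)
  expect_error(writhe(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "zero-length")
})

test_that("twist sums junction angles and is additive", {
  conf <- twisted_circle(334, -7)
  expect_equal(twist(conf), -7, tolerance = 1e-9)
  expect_equal(twist(conf$twist[1:100]) + twist(conf$twist[101:334]),
               twist(conf), tolerance = 1e-12)
  expect_equal(twist(rep(0, 50)), 0)
})

test_that("supercoiling density reproduces the printed values", {
  expect_equal(supercoiling_density(-7, 3000, 10.5), -0.0245)
  expect_equal(supercoiling_density(-14, 3000, 10.5), -0.049)
  # rounding to the nearest 0.005 gives the printed -0.025 and -0.05
  expect_equal(round(supercoiling_density(-7, 3000) / 0.005) * 0.005, -0.025)
  expect_equal(round(supercoiling_density(-14, 3000) / 0.005) * 0.005, -0.05)
  expect_equal(supercoiling_density(0, 2686, 10.4), 0)
})

test_that("topology record keeps Lk = Tw + Wr as an identity", {
  topo <- ring_topology(334, delta_lk = -7)
  rec <- topology_record(twisted_circle(334, -7), topo)
  expect_equal(rec$lk, rec$tw + rec$wr)
  expect_equal(rec$lk, -7, tolerance = 1e-9)
  expect_equal(rec$sigma, supercoiling_density(-7, 3000, 10.5),
               tolerance = 1e-9)
})
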