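test_that("asphericity and prolateness reproduce the limit cases", {
  expect_equal(asphericity(c(1, 1, 1)), 0)        # perfect sphere
  expect_equal(asphericity(c(2, 1, 1)), 0.0625)
  expect_equal(asphericity(c(1, 1, 0)), 0.25)     # flat disc
  expect_equal(prolateness(c(2, 1, 1)), 1)        # perfectly prolate
  expect_equal(prolateness(c(1, 1, 0.5)), -1)     # perfectly oblate
  expect_equal(prolateness(c(3, 2, 1)), 0)
  expect_equal(prolateness(c(1, 1, 1)), 0)        # 0/0 convention
  expect_error(asphericity(c(0, 0, 0)), "degenerate")
})

test_that("shape descriptors are scale-free and bounded", {
  set.seed(6)
  for (k in 1:200) {
    ax <- sort(runif(3, 1e-3, 10), decreasing = TRUE)
    A <- asphericity(ax)
    P <- prolateness(ax)
    expect_gte(A, 0); expect_lte(A, 1)
    expect_gte(P, -1); expect_lte(P, 1)
    lam <- runif(1, 0.01, 100)
    expect_equal(asphericity(lam * ax), A, tolerance = 1e-12)
    expect_equal(prolateness(lam * ax), P, tolerance = 1e-9)
  }
})

test_that("inertial ellipsoid solves the hollow-shell moment relations", {
  # two antipodal clusters: degenerate rod, a ~ d, b = c ~ 0
  d <- 3
  rod <- rbind(matrix(rep(c(d, 0, 0), 50), ncol = 3, byrow = TRUE),
               matrix(rep(c(-d, 0, 0), 50), ncol = 3, byrow = TRUE))
  ax <- suppressWarnings(inertial_ellipsoid(rod))
  expect_equal(as.numeric(ax[1]), sqrt(3) * d, tolerance = 1e-9)
  expect_lt(ax[2], 1e-6)
  # coplanar points: c ~ 0, no error
  flat <- cbind(rnorm(100), rnorm(100), 0)
  expect_lt(inertial_ellipsoid(flat)[3], 1e-9)
})

test_that("2D asphericity matches a direct gyration-tensor oracle", {
  th <- 2 * pi * (1:1000) / 1000
  expect_lt(asphericity_2d(cbind(cos(th), sin(th))), 1e-3)
  expect_equal(asphericity_2d(cbind(1:10, 2 * (1:10))), 1)
  set.seed(12)
  pts <- cbind(2 * cos(th), sin(th)) %*%
    matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2)
  # oracle: explicit tensor, eigenvalues by hand from the 2x2 closed form
  d <- sweep(pts, 2, colMeans(pts))
  S <- crossprod(d) / nrow(d)
  tr <- S[1, 1] + S[2, 2]
  disc <- sqrt((S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2)
  lam <- c((tr + disc) / 2, (tr - disc) / 2)
  expect_equal(asphericity_2d(pts),
               (lam[1] - lam[2])^2 / (lam[1] + lam[2])^2,
               tolerance = 1e-12)
  expect_error(asphericity_2d(matrix(1, 5, 2)), "identical")
})

test_that("frequency density integrates to one", {
  set.seed(2)
  v <- rnorm(5000)
  prof <- frequency_density(v)
  widths <- diff(prof$bin_center)[1]
  expect_equal(sum(prof$density) * widths, 1, tolerance = 1e-12)
  one <- frequency_density(5)
  expect_equal(nrow(one), 1)
  expect_error(frequency_density(numeric(0)), "values")
  flat <- frequency_density(runif(20000), bins = seq(0, 1, 0.1))
  expect_true(all(abs(flat$density - 1) < 0.1))
})
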