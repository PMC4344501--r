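test_that("a free bead obeys the Einstein relation at kT = 1", {
  st <- system_state(list(ring_conformation(matrix(0, 1, 3),
                                            closed = FALSE)))
  set.seed(7)
  msd <- mean(replicate(300, {
    tr <- bd_run(st, proto = run_protocol(n_steps = 2000,
                                          sample_every = 2000,
                                          seed = NA, dt = 1e-3),
                 excluded_volume = FALSE)
    sum(tr$frames[[1]][1, ]^2)
  }))
  expect_equal(msd, 6 * 1e-3 * 2000, tolerance = 0.1)
})

test_that("a bonded dimer samples the harmonic-bond Boltzmann distribution", {
  st <- system_state(list(ring_conformation(rbind(c(0, 0, 0), c(1, 0, 0)),
                                            closed = FALSE)))
  tr <- bd_run(st, proto = run_protocol(n_steps = 2e5, sample_every = 100,
                                        seed = 13),
               excluded_volume = FALSE)
  bl <- vapply(tr$frames, function(p) sqrt(sum((p[2, ] - p[1, ])^2)),
               numeric(1))
  # p(r) ~ r^2 exp(-k(r-1)^2/2): mean ~ r0 + 2/(k r0), sd ~ 1/sqrt(k)
  expect_equal(mean(bl), 1 + 2 / 800, tolerance = 0.005)
  expect_equal(sd(bl), sqrt(1 / 800), tolerance = 0.15)
})

test_that("identical seed and configuration give identical trajectories", {
  st <- system_state(list(planar_circle(64)))
  p <- run_protocol(n_steps = 2000, sample_every = 500, seed = 3)
  t1 <- bd_run(st, proto = p)
  t2 <- bd_run(st, proto = p)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energy, t2$energy)
})

test_that("instability (per-step displacement above half a diameter) aborts", {
  conf <- ring_conformation(rbind(c(0, 0, 0), c(3, 0, 0)), closed = FALSE)
  st <- system_state(list(conf))
  ff <- force_field(k_bond = 5e6)     # absurd stiffness at this dt
  expect_error(bd_run(st, ff, run_protocol(n_steps = 10, seed = 1),
                      excluded_volume = FALSE),
               "instability")
})

test_that("linking number Lk = Tw + Wr is conserved along BD trajectories", {
  topo <- ring_topology(334, delta_lk = -7)
  st <- init_system(topo, m_rings = 1, phi = 0)
  tr <- bd_run(st, proto = run_protocol(n_steps = 3e4, sample_every = 1500,
                                        seed = 11))
  tw <- vapply(tr$twist, function(v) sum(v) / (2 * pi), numeric(1))
  wr <- vapply(tr$frames, writhe, numeric(1))
  expect_true(all(abs(tw + wr - (-7)) < 0.05))
  # and twist actually flows into writhe (the ring starts at Wr = 0)
  expect_gt(max(abs(wr)), 1e-3)
})

test_that("molecules unwrap exactly across periodic boundaries", {
  topo <- ring_topology(64, delta_lk = NA)
  st <- init_system(topo, m_rings = 2, phi = 0.05, seed = 3)
  tr <- bd_run(st, proto = run_protocol(n_steps = 5000, sample_every = 2500,
                                        seed = 4))
  fin <- tr$final_state
  up <- unwrap_molecules(fin)
  for (p in up) {
    n <- nrow(p)
    bl <- sqrt(rowSums((p[c(2:n, 1), ] - p)^2))
    expect_true(all(bl < 2))
  }
  # round trip wrap(unwrap(x)) = x
  w <- wrap_coordinates(up, fin$box_length)
  expect_equal(w$pos[[1]], fin$rings[[1]]$pos, tolerance = 1e-12)
  expect_equal(w$flags[[2]], fin$image_flags[[2]])
  # corrupted flags are caught
  bad <- fin
  bad$image_flags[[1]][5, 1] <- bad$image_flags[[1]][5, 1] + 3L
  expect_error(unwrap_molecules(bad), "corrupted")
})

test_that("box compression hits the target volume fraction exactly", {
  st <- init_system(ring_topology(64, delta_lk = NA), m_rings = 2,
                    phi = 0.05, seed = 3)
  expect_equal(volume_fraction(st), 0.05, tolerance = 1e-12)
  # no-op when already at the target
  expect_identical(compress_box(st, 0.05), st)
  proto <- run_protocol(n_steps = 0, compression_interval = 300, seed = 4)
  stc <- compress_box(st, 0.10, proto = proto)
  expect_equal(volume_fraction(stc), 0.10, tolerance = 1e-3 * 0.10)
  # halving the volume means a box-length ratio of 2^(1/3)
  expect_equal(st$box_length / stc$box_length, 2^(1 / 3), tolerance = 1e-6)
})

test_that("equilibration detection flags plateaus and drifts correctly", {
  expect_equal(detect_equilibration(matrix(5, 100, 3)), 0L)
  stepser <- c(rep(10, 8), rep(5, 92))
  k <- detect_equilibration(cbind(stepser, stepser))
  expect_gte(k, 8L)
  expect_lte(k, 8L + 5L)            # within [k, k + window]
  expect_warning(res <- detect_equilibration(matrix(1:100, 100, 1)),
                 "not equilibrated")
  expect_true(is.na(res))
  expect_error(detect_equilibration(matrix(1, 5, 1)), "short")
})

test_that("trajectories round-trip through extended XYZ losslessly", {
  topo <- ring_topology(64, delta_lk = -2)
  st <- init_system(topo, m_rings = 2, phi = 0.05, seed = 3)
  tr <- bd_run(st, proto = run_protocol(n_steps = 3000, sample_every = 1000,
                                        seed = 2))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  tr2 <- read_xyz(f)
  for (k in seq_along(tr$frames)) {
    expect_equal(tr2$frames[[k]], tr$frames[[k]], tolerance = 1e-13)
    expect_equal(tr2$twist[[k]], tr$twist[[k]], tolerance = 1e-13)
  }
  expect_identical(tr2$steps, tr$steps)
  expect_equal(tr2$box, tr$box, tolerance = 1e-13)
  # empty trajectory round-trips
  e <- sc_trajectory(list(), ring_len = 64, closed = TRUE, torsion = FALSE,
                     steps = integer())
  write_xyz(e, f)
  expect_equal(length(read_xyz(f)$frames), 0)
  # truncation is reported with the frame index
  write_xyz(tr, f)
  ln <- readLines(f)
  writeLines(ln[1:(length(ln) - 10)], f)
  expect_error(read_xyz(f), "frame 3")
})

test_that("dilute multi-ring systems match independent single-ring runs", {
  topo <- ring_topology(48, delta_lk = NA)
  st <- init_system(topo, m_rings = 3, phi = 0)
  tr <- bd_run(st, proto = run_protocol(n_steps = 4000, sample_every = 2000,
                                        seed = 21))
  expect_equal(length(tr$ring_len), 3)
  expect_equal(dim(tr$rg), c(2, 3))
  # molecules evolve independently: no inter-ring forces at infinite box
  expect_false(is.finite(tr$box))
})
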