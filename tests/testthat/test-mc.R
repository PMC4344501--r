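test_that("MC and BD sample the same bending-energy distribution", {
  # detailed-balance sanity: the Metropolis sampler and the Brownian
  # integrator share one Hamiltonian, so ensemble averages must agree
  st <- system_state(list(planar_circle(64)))
  trb <- bd_run(st, proto = run_protocol(n_steps = 3e5, sample_every = 1000,
                                         seed = 2))
  eb <- trb$energy[100:300, "bend"]
  trm <- mc_sample(st, n_sweeps = 6000, sample_every = 10, seed = 2)
  em <- rowSums(trm$bend_energy)[200:600]
  # conservative effective-sample counts for the standard errors
  se <- sqrt(sd(eb)^2 / 30 + sd(em)^2 / 20)
  expect_lt(abs(mean(eb) - mean(em)), 3 * se)
})

test_that("MC sampling is reproducible and moves are accepted sanely", {
  st <- system_state(list(planar_circle(48)))
  a <- mc_sample(st, n_sweeps = 200, sample_every = 50, seed = 5)
  b <- mc_sample(st, n_sweeps = 200, sample_every = 50, seed = 5)
  expect_identical(a$frames, b$frames)
  expect_gt(a$acc[2], 0.3)          # crankshaft
  expect_gt(a$acc[1], 0.2)          # local displacement
  # bonds stay near their rest length under the move mix
  p <- a$frames[[4]]
  bl <- sqrt(rowSums((p[c(2:48, 1), ] - p)^2))
  expect_true(all(abs(bl - 1) < 0.2))
})

test_that("fixed-linking MC partitions twist into writhe like explicit-frame BD", {
  # same ring, two torsion treatments: explicit material frames (BD)
  # versus the homogeneous-twist free energy on the writhe (MC)
  topo <- ring_topology(64, delta_lk = -4, n_bp = 64 * 3000 / 334)
  set.seed(21)
  st <- init_system(topo, 1, 0, seed = NA)
  trb <- bd_run(st, proto = run_protocol(n_steps = 4e5, sample_every = 2000,
                                         seed = NA))
  wr_bd <- vapply(trb$frames, writhe, numeric(1))[100:200]
  trm <- mc_sample(st, n_sweeps = 10000, sample_every = 50, delta_lk = -4,
                   seed = NA)
  wr_mc <- trm$wr[100:200, 1]
  se <- sqrt(sd(wr_bd)^2 / 10 + sd(wr_mc)^2 / 10)
  expect_lt(abs(mean(wr_bd) - mean(wr_mc)), 3 * se)
  # both develop substantial negative writhe from the deficit
  expect_lt(mean(wr_bd), -1)
  expect_lt(mean(wr_mc), -1)
})

test_that("incrementally tracked writhe matches the exact recomputation", {
  topo <- ring_topology(48, delta_lk = -2, n_bp = 48 * 3000 / 334)
  st <- init_system(topo, 1, 0, seed = 3)
  tr <- mc_sample(st, n_sweeps = 500, sample_every = 100, delta_lk = -2,
                  seed = 7)
  # $wr is recomputed exactly at sampling; the final state's polygon
  # writhe must agree with the last sample
  fin <- unwrap_molecules(tr$final_state)[[1]]
  expect_equal(writhe(fin), tr$wr[nrow(tr$wr), 1], tolerance = 1e-9)
})
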