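test_that("make_phantom satisfies its structural invariants", {
  for (geom in c("nested-spheres", "blocks")) {
    ph <- make_phantom(c(16, 16, 12), geometry = geom)
    expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L, 2L, 3L))
    fg <- ph$labels > 0L
    expect_true(all(ph$t1[fg] > 0) && all(ph$m0[fg] > 0))
    expect_true(all(ph$t1[!fg] == 0) && all(ph$m0[!fg] == 0))
    expect_true(all(ph$perfusion[ph$labels == 0L | ph$labels == 3L] == 0))
    expect_identical(dim(ph$t1), dim(ph$labels))
    expect_identical(dim(ph$perfusion), dim(ph$labels))
  }
})

test_that("make_phantom applies the requested tissue values and is deterministic", {
  ph <- make_phantom(c(32, 32, 16),
                     t1_by_tissue = c(gm = 1442.8, wm = 900.2, csf = 4042.9))
  expect_true(all(ph$t1[ph$labels == 1L] == 1442.8))
  expect_true(all(ph$t1[ph$labels == 2L] == 900.2))
  expect_true(all(ph$t1[ph$labels == 3L] == 4042.9))

  a <- make_phantom(c(8, 8, 8), t1_spread = 0.05, seed = 42L)
  b <- make_phantom(c(8, 8, 8), t1_spread = 0.05, seed = 42L)
  expect_identical(a, b)
  c2 <- make_phantom(c(8, 8, 8), t1_spread = 0.05, seed = 43L)
  expect_false(identical(a$t1, c2$t1))
})

test_that("make_phantom rejects invalid parameters", {
  expect_error(make_phantom(c(4, 8, 8)), class = "aslbs_parameter_error")
  expect_error(make_phantom(c(8, 8, 8), t1_by_tissue = c(gm = -5, wm = 900, csf = 4000)),
               class = "aslbs_parameter_error")
  expect_error(make_phantom(c(8, 8, 8), m0_by_tissue = c(gm = 0, wm = 1, csf = 1)),
               class = "aslbs_parameter_error")
})

test_that("acq_config validates its fields", {
  expect_error(acq_config(fa_low = 20, fa_high = 9), class = "aslbs_parameter_error")
  expect_error(acq_config(fa_low = 9, fa_high = 9), class = "aslbs_parameter_error")
  expect_error(acq_config(tr = -1), class = "aslbs_parameter_error")
  expect_silent(cfg <- acq_config())
  expect_equal(cfg$labeling_duration + cfg$post_labeling_delay, 3700)
})

test_that("noiseless simulate_spgr matches the closed-form oracle voxelwise", {
  ph <- make_phantom(c(16, 16, 8))
  for (tr in c(15, 4000)) {
    cfg <- acq_config(tr_excitation = tr)
    for (fa in c(9, 20)) {
      s <- simulate_spgr(ph, cfg, fa)
      expected <- array(0, dim = dim(ph$t1))
      fg <- ph$labels > 0L
      expected[fg] <- oracle_spgr(ph$t1[fg], ph$m0[fg], tr, fa)
      expect_lt(max(abs(s - expected) / pmax(abs(expected), 1e-300)), 1e-12)
      expect_true(all(is.finite(s)) && all(s >= 0))
    }
  }
})

test_that("simulate_spgr limits behave: T1 -> Inf kills signal, full recovery -> M0", {
  expect_lt(oracle_spgr(1e12, 1, 4000, 20), 1e-7)
  # fa near 90 and TR >> T1: signal approaches M0
  expect_equal(oracle_spgr(500, 1, 1e7, 89.999), 1, tolerance = 1e-6)
  ph <- make_phantom(c(8, 8, 8), t1_by_tissue = c(gm = 1e9, wm = 1e9, csf = 1e9))
  s <- simulate_spgr(ph, acq_config(), 20)
  expect_lt(max(abs(s)), 1e-7)
})

test_that("simulate_spgr rejects flip angles outside (0, 90) and seeds its noise", {
  ph <- make_phantom(c(8, 8, 8))
  cfg <- acq_config()
  expect_error(simulate_spgr(ph, cfg, 0), class = "aslbs_parameter_error")
  expect_error(simulate_spgr(ph, cfg, 90), class = "aslbs_parameter_error")
  s1 <- simulate_spgr(ph, cfg, 20, noise_sigma = 0.01, seed = 5)
  s2 <- simulate_spgr(ph, cfg, 20, noise_sigma = 0.01, seed = 5)
  s3 <- simulate_spgr(ph, cfg, 20, noise_sigma = 0.01, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("simulate_asl_pair: null perfusion and zero noise give an exactly zero difference", {
  ph <- make_phantom(c(8, 8, 8),
                     perfusion_by_tissue = c(gm = 0, wm = 0, csf = 0))
  cfg <- acq_config(noise_sigma = 0)
  sched <- bs_schedule(c(1800, 3200))
  sim <- simulate_asl_pair(ph, cfg, sched, n_repeats = 3, physio_noise = 0)
  expect_true(all(sim$diff == 0))
})

test_that("simulate_asl_pair: even pulse count restores the perfusion sign", {
  ph <- make_phantom(c(8, 8, 8))
  cfg <- acq_config()
  sim2 <- simulate_asl_pair(ph, cfg, bs_schedule(c(1800, 3200)),
                            n_repeats = 1, physio_noise = 0)
  expect_gt(mean(sim2$diff[ph$labels == 1L]), 0)
  expect_equal(sim2$perfusion_scale, 1)
  sim1 <- simulate_asl_pair(ph, cfg, bs_schedule(2800),
                            n_repeats = 1, physio_noise = 0)
  expect_equal(sim1$perfusion_scale, -1)
})

test_that("simulate_asl_pair under perfect suppression recovers scaled perfusion", {
  # all three tissues share the two nulled T1s, so static signal vanishes
  opt <- optimize_schedule(2, c(1442.8, 900.2))
  ph <- make_phantom(c(12, 12, 8),
                     t1_by_tissue = c(gm = 1442.8, wm = 900.2, csf = 1442.8))
  cfg <- acq_config(noise_sigma = 0.005)
  n_rep <- 100
  sim <- simulate_asl_pair(ph, cfg, opt$schedule, n_repeats = n_rep,
                           physio_noise = 0.02, seed = 11)
  gm <- ph$labels == 1L
  expected <- ph$perfusion[gm][1] * sim$perfusion_scale
  thermal <- cfg$noise_sigma * mean(ph$m0[ph$labels > 0])
  se <- thermal * sqrt(2 / n_rep) / sqrt(sum(gm))   # SE of the GM-mean difference
  expect_lt(abs(mean(sim$diff[gm]) - expected), 3 * se)
})

test_that("simulate_asl_pair is deterministic per seed and validates inputs", {
  ph <- make_phantom(c(8, 8, 8))
  cfg <- acq_config()
  sched <- bs_schedule(c(1800, 3200))
  a <- simulate_asl_pair(ph, cfg, sched, n_repeats = 2, physio_noise = 0.01, seed = 3)
  b <- simulate_asl_pair(ph, cfg, sched, n_repeats = 2, physio_noise = 0.01, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_asl_pair(ph, cfg, sched, n_repeats = 0),
               class = "aslbs_parameter_error")
  expect_error(simulate_asl_pair(ph, cfg, sched, physio_noise = -0.1),
               class = "aslbs_parameter_error")
})
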