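test_that("mz_at_readout reproduces the analytic limits", {
  t1s <- c(300, 900.2, 1442.8, 4042.9)
  # equilibrium: no pulses, no saturation
  s0 <- bs_schedule(numeric(), presaturation = FALSE)
  expect_equal(mz_at_readout(s0, t1s), rep(1, 4))
  # saturation recovery
  ssat <- bs_schedule(numeric(), presaturation = TRUE)
  expect_equal(mz_at_readout(ssat, t1s), 1 - exp(-3700 / t1s), tolerance = 1e-12)
  # ideal inversion exactly at readout negates the no-pulse value
  sinv <- bs_schedule(3700, presaturation = TRUE)
  expect_equal(mz_at_readout(sinv, t1s), -(1 - exp(-3700 / t1s)), tolerance = 1e-12)
})

test_that("schedule construction rejects malformed pulse trains", {
  expect_error(bs_schedule(c(2000, 1000)), class = "aslbs_data_error")
  expect_error(bs_schedule(c(1000, 1000)), class = "aslbs_data_error")
  expect_error(bs_schedule(c(-5, 1000)), class = "aslbs_data_error")
  expect_error(bs_schedule(4000, readout_time = 3700), class = "aslbs_data_error")
  expect_error(bs_schedule(1000, inversion_efficiency = 0.4),
               class = "aslbs_parameter_error")
  expect_error(mz_at_readout(bs_schedule(1000), -100),
               class = "aslbs_parameter_error")
})

test_that("the power-form Euler integrator equals the literal step loop", {
  cases <- list(list(t = c(1800, 3200), t1 = 1442.8, eta = 1, pre = TRUE),
                list(t = 2800, t1 = 900.2, eta = 0.85, pre = TRUE),
                list(t = numeric(), t1 = 4042.9, eta = 1, pre = FALSE))
  for (cs in cases) {
    sched <- bs_schedule(cs$t, inversion_efficiency = cs$eta,
                         presaturation = cs$pre)
    expect_equal(mz_at_readout_euler(sched, cs$t1, dt = 0.5),
                 oracle_mz_euler_loop(cs$t, 3700, cs$t1, cs$eta, cs$pre, dt = 0.5),
                 tolerance = 1e-9)
  }
})

test_that("closed form matches the 0.01-ms Euler integrator on random schedules", {
  set.seed(20240901)
  worst <- 0
  for (i in 1:100) {
    sched <- random_schedule()
    t1 <- runif(1, 250, 4500)
    d <- abs(mz_at_readout(sched, t1) - mz_at_readout_euler(sched, t1, dt = 0.01))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-4)
})

test_that("|Mz| stays within 1 and recovery between pulses is monotone", {
  set.seed(77)
  for (i in 1:25) {
    sched <- random_schedule()
    t1 <- runif(1, 250, 4500)
    expect_lte(abs(mz_at_readout(sched, t1)), 1)
  }
  # after the last pulse, Mz(t) must increase monotonically toward M0
  pulses <- c(800, 1900)
  t1 <- 1200
  ts <- seq(1950, 3700, by = 50)
  mzs <- vapply(ts, function(tt) {
    mz_at_readout(bs_schedule(pulses, readout_time = tt), t1)
  }, numeric(1))
  expect_true(all(diff(mzs) > 0))
  expect_true(all(mzs < 1))
})

test_that("single-pulse nulling matches the independent bisection root", {
  t1 <- 1442.8
  opt <- optimize_schedule(1, t1, grid_ms = 10)
  expect_lte(abs(opt$result$residual_mz[[1]]), 1e-6)
  # root of (2 - exp(-t/T1)) exp(-(T - t)/T1) = 1, found by plain bisection
  f <- function(t) (2 - exp(-t / t1)) * exp(-(3700 - t) / t1) - 1
  lo <- 0; hi <- 3700
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(opt$schedule$pulse_times, (lo + hi) / 2, tolerance = 1e-3)
})

test_that("zero pulses returns the saturation-recovery residuals", {
  t1s <- c(900.2, 1442.8)
  opt <- optimize_schedule(0, t1s)
  expect_length(opt$schedule$pulse_times, 0)
  expect_equal(unname(opt$result$residual_mz), 1 - exp(-3700 / t1s),
               tolerance = 1e-12)
})

test_that("two pulses null both gray and white matter T1s", {
  opt <- optimize_schedule(2, c(1442.8, 900.2), grid_ms = 25)
  expect_true(all(abs(opt$result$residual_mz) <= 1e-3))
  expect_length(opt$schedule$pulse_times, 2)
  expect_true(all(diff(opt$schedule$pulse_times) > 0))
})

test_that("optimizer beats a coarse independent grid oracle and random schedules", {
  t1s <- c(1442.8, 900.2)
  opt <- optimize_schedule(2, t1s, grid_ms = 25)
  # independent brute force on a 50-ms grid using the loop oracle recursion
  obj_loop <- function(times) {
    sum(vapply(t1s, function(t1) {
      mz <- 0; prev <- 0
      for (tp in times) {
        mz <- 1 + (mz - 1) * exp(-(tp - prev) / t1)
        mz <- -mz
        prev <- tp
      }
      (1 + (mz - 1) * exp(-(3700 - prev) / t1))^2
    }, numeric(1)))
  }
  grid <- seq(0, 3700, by = 50)
  best <- Inf
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[j] > grid[i]) best <- min(best, obj_loop(c(grid[i], grid[j])))
    }
  }
  expect_lte(opt$result$objective, best + 1e-12)

  set.seed(123)
  rand_best <- min(vapply(1:1000, function(i) {
    obj_loop(sort(runif(2, 0, 3700)))
  }, numeric(1)))
  expect_lte(opt$result$objective, rand_best)
})

test_that("optimization is deterministic and capped combinatorics error out", {
  a <- optimize_schedule(2, c(1442.8, 900.2), grid_ms = 25)
  b <- optimize_schedule(2, c(1442.8, 900.2), grid_ms = 25)
  expect_identical(a$schedule$pulse_times, b$schedule$pulse_times)
  expect_error(optimize_schedule(4, 1300, grid_ms = 1),
               class = "aslbs_parameter_error")
  expect_error(optimize_schedule(2, numeric()), class = "aslbs_parameter_error")
  expect_error(optimize_schedule(2, c(1300, -2)), class = "aslbs_parameter_error")
})

test_that("a schedule adapted to the subject dominates the fixed schedule", {
  fixed <- optimize_schedule(2, c(1300, 850))$schedule
  # volunteer 5 of the bundled cohort: the largest GM deviation
  subj <- c(1823, 974)
  adapted <- optimize_schedule(2, subj)$schedule
  cmp <- compare_schedules(fixed, adapted, subj)
  expect_true(cmp$adapted_not_worse)
  expect_lte(cmp$objective_adapted, cmp$objective_fixed)

  # same target set: both optimizations solve the same problem
  same <- compare_schedules(fixed, optimize_schedule(2, c(1300, 850))$schedule,
                            c(1300, 850))
  expect_equal(same$objective_ratio, 1, tolerance = 1e-6)
  # identical schedules: ratio exactly 1
  expect_equal(compare_schedules(fixed, fixed, subj)$objective_ratio, 1)
})

test_that("compare_schedules requires a shared timeline", {
  a <- bs_schedule(1000, readout_time = 3700)
  b <- bs_schedule(1000, readout_time = 3000)
  expect_error(compare_schedules(a, b, 1300), class = "aslbs_data_error")
})
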