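# Independent oracles and small fixtures used across the suite.
# These deliberately avoid the package's own code paths.

# Spoiled gradient echo closed form, written out once more by hand.
oracle_spgr <- function(t1, m0, tr, fa_deg) {
  a <- fa_deg * pi / 180
  m0 * sin(a) * (1 - exp(-tr / t1)) / (1 - exp(-tr / t1) * cos(a))
}

# Literal forward-Euler step loop for the longitudinal dynamics; slow, only
# for coarse dt on a few cases.
oracle_mz_euler_loop <- function(pulse_times, readout_time, t1,
                                 efficiency = 1, presaturation = TRUE,
                                 dt = 0.5) {
  events <- c(pulse_times, readout_time)
  mz <- if (presaturation) 0 else 1
  prev <- 0
  for (k in seq_along(events)) {
    len <- events[k] - prev
    if (len > 0) {
      n <- ceiling(len / dt)
      h <- len / n
      for (i in seq_len(n)) mz <- mz + h * (1 - mz) / t1
    }
    if (k <= length(pulse_times)) mz <- (1 - 2 * efficiency) * mz
    prev <- events[k]
  }
  mz
}

# Brute-force exact Wilcoxon signed-rank p by enumerating every sign vector.
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Random feasible schedule for property tests (seeded by the caller).
random_schedule <- function(readout_time = 3700) {
  n <- sample(0:4, 1)
  times <- sort(runif(n, 0, readout_time))
  while (n > 1 && any(diff(times) <= 0)) times <- sort(runif(n, 0, readout_time))
  bs_schedule(times, readout_time = readout_time,
              inversion_efficiency = runif(1, 0.6, 1),
              presaturation = sample(c(TRUE, FALSE), 1))
}

# A T1 map object built directly (bypassing the fit) for degenerate cases.
mock_t1_map <- function(t1, m0 = t1 * 0 + 1, valid = is.finite(t1) & t1 > 0) {
  t1 <- as.array(t1)
  structure(list(t1 = t1, m0 = array(m0, dim = dim(t1)),
                 valid = array(valid, dim = dim(t1))),
            class = "asl_t1_map")
}
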