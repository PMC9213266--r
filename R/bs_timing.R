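## Background suppression timing: closed-form longitudinal Bloch dynamics
## under a saturation pulse followed by inversion pulses, and optimization
## of the pulse times so that chosen tissue T1s are nulled at readout.
##
## Between events the longitudinal magnetization relaxes as
##   Mz(t) = M0 + (Mz+ - M0) exp(-dt/T1),
## a presaturation sets Mz(0) = 0, and an inversion pulse of efficiency eta
## maps Mz -> (1 - 2 eta) Mz.  Everything below works in units of M0 = 1.

#' Construct a background suppression schedule
#'
#' @param pulse_times Strictly increasing inversion pulse times in ms,
#'   offsets from the start of labeling; may be empty.  All times must lie
#'   in `[0, readout_time]`.
#' @param readout_time Time of image readout, ms (labeling duration plus
#'   post-labeling delay; default 2000 + 1700).
#' @param inversion_efficiency Fraction in (0.5, 1]; 1 is an ideal
#'   inversion.
#' @param presaturation Logical; if `TRUE` (default) the imaging volume is
#'   saturated (Mz = 0) at time 0, as at the start of pseudo-continuous
#'   ASL labeling.
#' @return Object of class `asl_bs_schedule`.
#' @examples
#' bs_schedule(c(1885.7, 3277.0))
#' @export
bs_schedule <- function(pulse_times = numeric(), readout_time = 3700,
                        inversion_efficiency = 1, presaturation = TRUE) {
  check_scalar_pos(readout_time, "readout_time")
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times)) {
    if (any(!is.finite(pulse_times)) || any(pulse_times < 0) ||
        any(pulse_times > readout_time)) {
      abort_data("pulse times must lie in [0, readout_time]")
    }
    if (any(diff(pulse_times) <= 0)) {
      abort_data("pulse times must be strictly increasing")
    }
  }
  if (!is.numeric(inversion_efficiency) || length(inversion_efficiency) != 1L ||
      inversion_efficiency <= 0.5 || inversion_efficiency > 1) {
    abort_param("`inversion_efficiency` must lie in (0.5, 1]")
  }
  structure(list(pulse_times = pulse_times,
                 readout_time = readout_time,
                 inversion_efficiency = inversion_efficiency,
                 presaturation = isTRUE(presaturation)),
            class = "asl_bs_schedule")
}

#' @export
print.asl_bs_schedule <- function(x, ...) {
  cat(sprintf("BS schedule: %s pulse(s) at [%s] ms, readout %g ms, eta %g%s\n",
              length(x$pulse_times),
              paste(sprintf("%.1f", x$pulse_times), collapse = ", "),
              x$readout_time, x$inversion_efficiency,
              if (x$presaturation) ", presaturated" else ""))
  invisible(x)
}

#' Longitudinal magnetization at readout (closed form)
#'
#' Piecewise-exponential solution of the longitudinal Bloch equation for a
#' presaturation + inversion-pulse train: relaxation
#' `Mz(t) = 1 + (Mz - 1) exp(-dt/T1)` between events, each pulse applying
#' `Mz -> (1 - 2 eta) Mz`.  Vectorized over `t1`.
#'
#' @param schedule A [bs_schedule()].
#' @param t1 Numeric vector of T1 values in ms, all > 0.
#' @return Signed residual magnetization at `readout_time` as a fraction
#'   of M0, one value per `t1`; always within `[-1, 1]`.
#' @examples
#' s <- bs_schedule(numeric(), presaturation = TRUE)
#' mz_at_readout(s, 1442.8)  # == 1 - exp(-3700/1442.8)
#' @export
mz_at_readout <- function(schedule, t1) {
  stopifnot(inherits(schedule, "asl_bs_schedule"))
  if (any(!is.finite(t1)) || any(t1 <= 0)) abort_param("all `t1` must be > 0")
  flip <- 1 - 2 * schedule$inversion_efficiency
  mz <- if (schedule$presaturation) rep(0, length(t1)) else rep(1, length(t1))
  prev <- 0
  for (tp in schedule$pulse_times) {
    mz <- 1 + (mz - 1) * exp(-(tp - prev) / t1)
    mz <- flip * mz
    prev <- tp
  }
  1 + (mz - 1) * exp(-(schedule$readout_time - prev) / t1)
}

#' Forward-Euler reference integrator for the longitudinal dynamics
#'
#' Independent cross-check of [mz_at_readout()]: integrates
#' `dMz/dt = (1 - Mz)/T1` with explicit Euler steps of (approximately)
#' `dt` ms between events.  Each inter-event segment is tiled with
#' `n = ceiling(len/dt)` equal steps `h = len/n`; the Euler recursion
#' `Mz <- Mz (1 - h/T1) + h/T1` is linear with constant coefficients, so
#' its n-step result is evaluated as `1 + (Mz0 - 1)(1 - h/T1)^n` — the
#' exact value the step loop would produce, without the loop.
#'
#' @inheritParams mz_at_readout
#' @param dt Target Euler step, ms (default 0.01).
#' @return Residual magnetization at readout, per `t1`.
#' @export
mz_at_readout_euler <- function(schedule, t1, dt = 0.01) {
  stopifnot(inherits(schedule, "asl_bs_schedule"))
  check_scalar_pos(dt, "dt")
  flip <- 1 - 2 * schedule$inversion_efficiency
  relax <- function(mz, len, t1) {
    if (len <= 0) return(mz)
    n <- ceiling(len / dt)
    h <- len / n
    g <- (1 - h / t1)^n
    1 + (mz - 1) * g
  }
  mz <- if (schedule$presaturation) rep(0, length(t1)) else rep(1, length(t1))
  prev <- 0
  for (tp in schedule$pulse_times) {
    mz <- relax(mz, tp - prev, t1)
    mz <- flip * mz
    prev <- tp
  }
  relax(mz, schedule$readout_time - prev, t1)
}

## Objective: sum_i w_i * Mz_i(readout)^2 (or max |Mz_i|), vectorized over a
## candidate matrix of pulse times (rows = candidates, columns = pulses in
## increasing order).
bs_objective_matrix <- function(times, t1s, weights, readout_time,
                                efficiency, presaturation,
                                metric = c("sumsq", "maxabs")) {
  metric <- match.arg(metric)
  if (!is.matrix(times)) times <- matrix(times, nrow = 1)
  flip <- 1 - 2 * efficiency
  acc <- rep(0, nrow(times))
  for (i in seq_along(t1s)) {
    t1 <- t1s[i]
    mz <- rep(if (presaturation) 0 else 1, nrow(times))
    prev <- rep(0, nrow(times))
    for (j in seq_len(ncol(times))) {
      mz <- 1 + (mz - 1) * exp(-(times[, j] - prev) / t1)
      mz <- flip * mz
      prev <- times[, j]
    }
    mz <- 1 + (mz - 1) * exp(-(readout_time - prev) / t1)
    acc <- if (metric == "sumsq") acc + weights[i] * mz^2 else pmax(acc, abs(mz))
  }
  acc
}

#' Optimize background suppression pulse times
#'
#' Finds pulse times in `[0, readout_time]` minimizing the weighted sum of
#' squared residual magnetizations `sum_i w_i (Mz_i(readout))^2` over the
#' target T1s, by exhaustive search over the ordered tuples of a coarse
#' time grid followed by local Nelder-Mead refinement.  Grid ties break to
#' the lexicographically smallest tuple, making the result deterministic.
#'
#' @param n_pulses Number of inversion pulses, 0 to 4 supported.
#' @param target_t1s T1 values (ms) to null, e.g. the subject's mean gray
#'   and white matter T1.
#' @param weights Non-negative weights, one per target (default all 1).
#' @param timeline Numeric pair `(labeling_duration, post_labeling_delay)`
#'   in ms; readout happens at their sum.
#' @param inversion_efficiency Fraction in (0.5, 1].
#' @param grid_ms Coarse grid spacing in ms (>= 1; default 25).
#' @param refine Run local refinement after the grid search (default TRUE).
#' @param presaturation Passed to [bs_schedule()].
#' @param metric `"sumsq"` (default) or `"maxabs"` objective.
#' @param max_candidates Cap on the number of grid tuples evaluated; an
#'   explicit error is raised when exceeded (never silent truncation).
#' @return List with `schedule` (the optimized [bs_schedule()]) and
#'   `result`, an `asl_suppression_result` holding the per-target
#'   `residual_mz` and the scalar `objective`.
#' @examples
#' opt <- optimize_schedule(2, c(1442.8, 900.2))
#' opt$result$residual_mz
#' @export
optimize_schedule <- function(n_pulses, target_t1s, weights = NULL,
                              timeline = c(2000, 1700),
                              inversion_efficiency = 1, grid_ms = 25,
                              refine = TRUE, presaturation = TRUE,
                              metric = c("sumsq", "maxabs"),
                              max_candidates = 5e6) {
  metric <- match.arg(metric)
  if (!is.numeric(n_pulses) || length(n_pulses) != 1L || n_pulses < 0 ||
      n_pulses != round(n_pulses) || n_pulses > 4) {
    abort_param("`n_pulses` must be an integer between 0 and 4")
  }
  if (!length(target_t1s) || any(!is.finite(target_t1s)) || any(target_t1s <= 0)) {
    abort_param("`target_t1s` must be non-empty and all > 0")
  }
  weights <- weights %||% rep(1, length(target_t1s))
  if (length(weights) != length(target_t1s) || any(weights < 0)) {
    abort_param("`weights` must match `target_t1s` and be non-negative")
  }
  if (grid_ms < 1) abort_param("`grid_ms` must be >= 1 ms")
  readout_time <- sum(timeline)
  check_scalar_pos(readout_time, "sum(timeline)")

  make_result <- function(times) {
    sched <- bs_schedule(times, readout_time = readout_time,
                         inversion_efficiency = inversion_efficiency,
                         presaturation = presaturation)
    res <- mz_at_readout(sched, target_t1s)
    obj <- if (metric == "sumsq") sum(weights * res^2) else max(abs(res))
    list(schedule = sched,
         result = structure(list(residual_mz = setNames(res, names(target_t1s) %||%
                                                          format(target_t1s)),
                                 objective = obj, metric = metric,
                                 target_t1s = target_t1s, weights = weights),
                            class = "asl_suppression_result"))
  }
  if (n_pulses == 0) return(make_result(numeric()))

  grid <- seq(0, readout_time, by = grid_ms)
  n_cand <- choose(length(grid), n_pulses)
  if (n_cand > max_candidates) {
    abort_param(sprintf(
      "grid search needs %.3g candidate tuples (> cap %.3g); increase `grid_ms` or `max_candidates`",
      n_cand, max_candidates))
  }
  cand <- t(combn(grid, n_pulses))
  obj <- bs_objective_matrix(cand, target_t1s, weights, readout_time,
                             inversion_efficiency, presaturation, metric)
  ## combn emits tuples in lexicographic order, so which.min is the
  ## lexicographically smallest minimizer
  best <- cand[which.min(obj), ]

  if (refine) {
    f <- function(p) {
      p <- sort(pmin(pmax(p, 0), readout_time))
      bs_objective_matrix(matrix(p, nrow = 1), target_t1s, weights,
                          readout_time, inversion_efficiency, presaturation,
                          metric)
    }
    if (n_pulses == 1) {
      o <- stats::optimize(function(x) f(x),
                           lower = max(0, best - 2 * grid_ms),
                           upper = min(readout_time, best + 2 * grid_ms),
                           tol = 1e-10)
      cand_ref <- o$minimum
    } else {
      o <- stats::optim(best, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
      cand_ref <- sort(pmin(pmax(o$par, 0), readout_time))
    }
    ## keep refinement only if it does not lose to the grid optimum
    if (f(cand_ref) <= min(obj)) best <- sort(cand_ref)
  }
  ## guard against refinement collapsing two pulses onto one time
  if (n_pulses > 1 && any(diff(best) <= 0)) {
    best <- best + cumsum(c(0, diff(best) <= 0)) * 1e-9
  }
  make_result(best)
}

#' @export
print.asl_suppression_result <- function(x, ...) {
  cat(sprintf("Residual Mz at readout (fraction of M0), objective (%s) = %.3g\n",
              x$metric, x$objective))
  print(signif(x$residual_mz, 4))
  invisible(x)
}

#' Compare a fixed and an individually adapted schedule on a subject
#'
#' Evaluates both schedules' residual magnetizations on the subject's own
#' tissue T1s and reports the per-T1 residuals, the two weighted
#' sum-of-squares objectives, their ratio, and whether the adapted
#' schedule is at least as good as the fixed one for this subject.
#'
#' @param fixed,adapted [bs_schedule()] objects sharing timeline
#'   (readout time) and presaturation setting.
#' @param subject_t1s The subject's T1 values, ms.
#' @param weights Optional weights (default all 1).
#' @return List with `residual_fixed`, `residual_adapted`,
#'   `objective_fixed`, `objective_adapted`, `objective_ratio`
#'   (adapted/fixed; 1 when both are zero) and `adapted_not_worse`.
#' @export
compare_schedules <- function(fixed, adapted, subject_t1s, weights = NULL) {
  stopifnot(inherits(fixed, "asl_bs_schedule"), inherits(adapted, "asl_bs_schedule"))
  if (!isTRUE(all.equal(fixed$readout_time, adapted$readout_time)) ||
      fixed$presaturation != adapted$presaturation) {
    abort_data("schedules must share readout time and presaturation")
  }
  weights <- weights %||% rep(1, length(subject_t1s))
  rf <- mz_at_readout(fixed, subject_t1s)
  ra <- mz_at_readout(adapted, subject_t1s)
  of <- sum(weights * rf^2)
  oa <- sum(weights * ra^2)
  ratio <- if (of == 0 && oa == 0) 1 else oa / of
  list(subject_t1s = subject_t1s,
       residual_fixed = rf, residual_adapted = ra,
       objective_fixed = of, objective_adapted = oa,
       objective_ratio = ratio,
       adapted_not_worse = oa <= of + 1e-12)
}
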