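test_that("parameter validation rejects undefined model configurations", {
  expect_s3_class(params_default(), "lysis_params")
  expect_error(lysis_params(0.2, 0.2, 1e-5, 12.5, 5e-6, 1e-4, 5e-3),
               "F0.*must exceed")
  expect_error(lysis_params(2, -1, 1e-5, 12.5, 5e-6, 1e-4, 5e-3), "Fstar")
  expect_error(lysis_params(2, 0.2, 0, 12.5, 5e-6, 1e-4, 5e-3), "Fbar0")
  expect_error(lysis_params(2, 0.2, 1e-5, 12.5, 5e-6, 6e-3, 5e-3), "Delta")
  # slices tile the clot exactly after rounding
  p <- lysis_params(2, 0.2, 1e-5, 12.5, 5e-6, 3e-4, 1e-3)
  expect_equal(p$n * p$Delta, p$L)
})

test_that("first-slice lysis time follows the accumulation integral", {
  # frozen hand evaluation: Delta = 1e-4, F0/F* = 12, k1 = 12.5,
  # u_f = 5e-6, Fbar0 = 1e-5  ->  sqrt(2e-4 log 12 / 6.25e-10)
  p <- lysis_params(F0 = 12, Fstar = 1, Fbar0 = 1e-5, k1 = 12.5,
                    u_f = 5e-6, Delta = 1e-4, L = 5e-3)
  expect_equal(first_slice_time(p), 891.72, tolerance = 1e-4)

  # F0 -> F* limit: no fibrin excess, instantaneous lysis
  p_eps <- lysis_params(F0 = 1 + 1e-12, Fstar = 1, Fbar0 = 1e-5, k1 = 12.5,
                        u_f = 5e-6, Delta = 1e-4, L = 5e-3)
  expect_lt(first_slice_time(p_eps), 1e-2)

  # sqrt(Delta) scaling: quadrupling Delta doubles t0 (L chosen so both
  # slicings tile the clot exactly)
  p1 <- params_default(Delta = 1e-4, L = 4.8e-3)
  p4 <- params_default(Delta = 4e-4, L = 4.8e-3)
  expect_equal(first_slice_time(p4) / first_slice_time(p1), 2,
               tolerance = 1e-12)
})

test_that("lysis schedule is increasing with decreasing gaps (front accelerates)", {
  p1 <- lysis_params(2, 0.2, 1e-5, 12.5, 5e-6, Delta = 5e-3, L = 5e-3)
  expect_length(lysis_schedule(p1), 1L)
  expect_equal(lysis_schedule(p1), first_slice_time(p1))

  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    s <- lysis_schedule(p)
    expect_length(s, p$n)
    expect_true(all(diff(s) > 0))
    if (p$n > 2L) expect_true(all(diff(diff(s)) < 1e-9 * s[1L]))
  }
})

test_that("telescoping identity holds to machine precision without advection", {
  p <- params_default()
  s <- lysis_schedule(p, advection = FALSE)
  a <- 2 * p$Delta * log(p$F0 / p$Fstar) / (p$k1 * p$u_f * p$Fbar0)
  expect_equal(diff(c(0, s^2)), rep(a, p$n), tolerance = 1e-12)
  # summed form: total time collapses to the closed form in L
  expect_equal(s[p$n], sqrt(2 * p$L * log(p$F0 / p$Fstar) /
                              (p$k1 * p$u_f * p$Fbar0)),
               tolerance = 1e-12)
})

test_that("total lysis time converges in the continuum (fine-slicing) limit", {
  # with the advection term retained, refining Delta leaves the total
  # time nearly unchanged once Delta << L
  p <- params_default(Delta = 1e-4)   # L/50
  tab <- delta_convergence(p, factors = c(1, 2))
  expect_equal(nrow(tab), 2L)
  expect_lt(attr(tab, "max_rel_spread"), 0.01)

  tab1 <- delta_convergence(p, factors = 1)
  expect_equal(nrow(tab1), 1L)

  # one big slice vs fine slicing: visibly different, reported not errored
  p_coarse <- params_default(Delta = 5e-3)
  tab2 <- delta_convergence(p_coarse, factors = c(1, 100))
  expect_gt(attr(tab2, "max_rel_spread"), 0.01)

  # closed-form limit at very fine slicing, advection negligible
  p_fast <- lysis_params(2.4, 0.2, 1e-5, 12.5, u_f = 1e-3,
                         Delta = 5e-3 / 1000, L = 5e-3)
  s <- lysis_schedule(p_fast)
  closed <- sqrt(2 * p_fast$L * log(p_fast$F0 / p_fast$Fstar) /
                   (p_fast$k1 * p_fast$u_f * p_fast$Fbar0))
  expect_equal(s[p_fast$n], closed, tolerance = 0.01)
})

test_that("front position is the piecewise-constant inverse of the schedule", {
  p <- params_default()
  s <- lysis_schedule(p)
  expect_equal(front_position(p, 0), 0)
  expect_equal(front_position(p, s[1L] * 0.999), 0)
  expect_equal(front_position(p, s[1L] + 1e-9), p$Delta)
  expect_equal(front_position(p, s[p$n]), p$L)
  expect_equal(front_position(p, s[p$n] * 10), p$L)
  expect_error(front_position(p, -1), "non-negative")
})

test_that("k1 is recovered from self-generated front trajectories", {
  p_true <- params_default(k1 = 12.5)
  s <- lysis_schedule(p_true)
  times <- seq(30, max(s) * 1.02, by = 30)
  traj <- data.frame(time_s = times,
                     position_m = front_position(p_true, times))
  fit <- fit_k1(traj, params_default(k1 = 1))
  expect_lt(abs(fit$k1_hat - 12.5) / 12.5, 0.01)
  expect_lt(fit$rms_residual_m, p_true$Delta)

  # 5% multiplicative noise, seeded: recovery within 10%
  p_noisy <- params_default(k1 = 18.67)
  s2 <- lysis_schedule(p_noisy)
  times2 <- seq(30, max(s2) * 1.02, by = 30)
  set.seed(7)
  traj2 <- data.frame(
    time_s = times2,
    position_m = front_position(p_noisy, times2) *
      (1 + 0.05 * stats::rnorm(length(times2))))
  fit2 <- fit_k1(traj2, params_default(k1 = 1))
  expect_lt(abs(fit2$k1_hat - 18.67) / 18.67, 0.10)

  # degenerate trajectory carries no information
  expect_error(fit_k1(data.frame(time_s = 1:5, position_m = numeric(5)),
                      p_true), "degenerate")
})

test_that("schedule depends on k1 and Fbar0 only through their product", {
  p1 <- params_default(k1 = 12.5)
  p2 <- params_default(k1 = 125)
  p2$Fbar0 <- p1$Fbar0 / 10
  expect_equal(lysis_schedule(p1), lysis_schedule(p2), tolerance = 1e-12)
})

test_that("front trajectories round-trip through delimited text", {
  p <- params_default()
  times <- seq(60, 4000, by = 60)
  traj <- data.frame(time_s = times, position_m = front_position(p, times))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# front positions from a bench run",
               "time_s\tposition_m",
               paste(traj$time_s, traj$position_m, sep = "\t")), f)
  rd <- read_front_trajectory(f)
  expect_equal(rd, traj)

  # headerless comma-separated variant
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(traj, f2, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  rd2 <- read_front_trajectory(f2)
  expect_equal(rd2, traj)
})
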