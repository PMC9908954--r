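test_that("group presets reproduce the published parameter table", {
  shared <- list(a = 338.9952, b = 2.2707, c = 7.1531, tau = 0.0250)
  for (g in c("3", "4", "6B")) {
    p <- cs_group_params(g)
    expect_equal(p[c("a", "b", "c", "tau")], shared)
    expect_equal(p$d, -27.9311)
  }
  p6a <- cs_group_params("6A")
  expect_equal(p6a[c("a", "b", "c", "tau")], shared)
  expect_equal(p6a$d, -17.9311)
})

test_that("parameter validation rejects degenerate values", {
  expect_error(cs_params(1, 2, 3, 4, tau = 0), "tau")
  expect_error(cs_params(1, b = -1, 3, 4, 0.1), "b")
  expect_error(cs_params(1, 2, 3, NA, 0.1), "finite")
})

test_that("steady-state discharge and tonic thresholds match closed forms", {
  p3 <- cs_group_params("3")
  expect_equal(steady_state_discharge(0, p3), 0)
  expect_equal(steady_state_discharge(5, p3), 7.8344, tolerance = 1e-8)
  expect_equal(tonic_threshold(p3), 3.9048, tolerance = 1e-4)
  expect_equal(tonic_threshold(cs_group_params("6A")), 2.5067,
               tolerance = 1e-4)
  # 6A discharges tonically at loads where 6B does not
  u_mid <- 3.2
  expect_gt(steady_state_discharge(u_mid, cs_group_params("6A")), 0)
  expect_equal(steady_state_discharge(u_mid, cs_group_params("6B")), 0)
})

test_that("discharge step validates inputs and handles the trivial cases", {
  p <- cs_group_params("3")
  st <- list(u = 0, x = 0)
  expect_equal(discharge_step(st, 0, 1 / 60, p)$y, 0)
  expect_error(discharge_step(st, NaN, 1 / 60, p), "finite")
  expect_error(discharge_step(st, 1, -0.1, p), "dt")
  expect_error(simulate_discharge(c(0, 1), c(0, 1, 2), p), "length")
  # at the instant of a step, before the threshold can move, y jumps to
  # (a + c) u + d
  u0 <- 5
  y_jump <- max(0, (p$a + p$c) * u0 + p$d)
  st_after <- discharge_step(list(u = 0, x = 0), u0, dt = 1e-9, p)
  expect_equal(st_after$y, y_jump, tolerance = 1e-4)
})

test_that("threshold trajectory matches the closed-form power-law solution", {
  p <- cs_group_params("3")
  t <- grid60(2)
  tr <- simulate_discharge(rep(5, length(t)), t, p, x0 = 0)
  e_num <- 5 - tr$x
  e_ref <- threshold_gap_closed_form(t[-1], 5, p$b, p$tau)
  expect_lt(max(abs(e_num[-1] - e_ref) / e_ref), 1e-3)
})

test_that("output is rectified nonnegative for arbitrary inputs", {
  set.seed(42)
  for (g in c("3", "6A")) {
    p <- cs_group_params(g)
    for (k in 1:5) {
      t <- grid60(2)
      u <- stats::rnorm(length(t), sd = 4) + 3 * sin(2 * pi * t)
      tr <- simulate_discharge(u, t, p, x0 = u[1])
      expect_true(all(tr$y >= 0))
    }
  }
})

test_that("threshold approaches a constant input monotonically, never crossing", {
  p <- cs_group_params("3")
  t <- grid60(1)
  for (u0 in c(2, 5, 10, -4)) {
    tr <- simulate_discharge(rep(u0, length(t)), t, p, x0 = 0)
    gap <- abs(u0 - tr$x)
    expect_true(all(diff(gap) <= 1e-12))
    expect_true(all(sign(u0 - tr$x) == sign(u0) | tr$x == u0))
  }
})

test_that("step response adapts monotonically to the steady state", {
  p <- cs_group_params("3")
  t <- grid60(3)
  u0 <- 10   # full-scale step
  tr <- simulate_discharge(rep(u0, length(t)), t, p, x0 = 0)
  ipk <- which.max(tr$y)
  expect_true(all(diff(tr$y[ipk:length(t)]) <= 1e-9))
  # settles into a 1%-of-response-amplitude band of the analytic steady state
  # after 20 time constants (the power-law tail rules out a tighter band)
  yss <- steady_state_discharge(u0, p)
  band <- 0.01 * (max(tr$y) - yss)
  late <- tr$y[t >= 20 * p$tau]
  expect_lt(max(abs(late - yss)), band)
})

test_that("peak discharge is non-decreasing in ramp rate", {
  p <- cs_group_params("3")
  ramps <- c(4, 2, 1, 0.5, 0.25)
  peaks <- vapply(ramps, function(rmp) {
    t <- grid60(rmp + 3)
    u <- trapezoid_input(t, amplitude = 5, t_on = 0.2, ramp = rmp, hold = 2)
    max(simulate_discharge(u, t, p)$y)
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("triangular cycling shows hysteresis between rising and falling limbs", {
  p <- cs_group_params("3")
  t <- grid60(4)
  period <- 2
  u <- 5 * (1 - abs((t %% period) / period * 2 - 1))   # triangle 0..5..0
  tr <- simulate_discharge(u, t, p, x0 = 0)
  # compare y at matched input level on the two limbs of the second cycle
  cyc2 <- t >= period & t < 2 * period
  rising <- cyc2 & c(0, diff(u)) > 0
  falling <- cyc2 & c(0, diff(u)) < 0
  u_probe <- 2.5
  y_up <- tr$y[rising][which.min(abs(tr$u[rising] - u_probe))]
  y_dn <- tr$y[falling][which.min(abs(tr$u[falling] - u_probe))]
  expect_gt(abs(y_up - y_dn), 50)
})

test_that("halving the integration step leaves the trapezoid peak unchanged", {
  p <- cs_group_params("3")
  t <- grid60(4)
  u <- trapezoid_input(t, amplitude = 5)
  pk1 <- max(simulate_discharge(u, t, p, substeps = 10)$y)
  pk2 <- max(simulate_discharge(u, t, p, substeps = 20)$y)
  expect_lt(abs(pk2 - pk1) / pk1, 0.01)
})

test_that("ramp-hold-release drives a phasic burst, adaptation, then silence", {
  p <- cs_group_params("3")
  t <- grid60(5)
  u <- trapezoid_input(t, amplitude = 5, t_on = 0.5, ramp = 0.5, hold = 2)
  tr <- simulate_discharge(u, t, p, x0 = 0)
  hold_end <- tr$y[which.min(abs(t - 2.9))]
  expect_gt(max(tr$y), 5 * hold_end)           # burst dominates the hold
  expect_true(all(tr$y[t > 3.6] == 0))         # silent during/after release
  expect_true(all(tr$y[t < 0.5] == 0))         # silent at baseline
})

test_that("group bank maps channels to groups and reproduces step phenomenology", {
  rec <- baseline_3step()
  d <- group_bank(rec)
  expect_named(d, c("3", "4", "6B", "6A"))
  # zero strain record -> all groups silent
  n <- 200
  z <- strain_record(t = (0:(n - 1)) / 60, phase = rep("swing", n),
                     tf_axial = rep(0, n), tf_transverse = rep(0, n),
                     tib_axial = rep(0, n), tib_transverse = rep(0, n))
  dz <- group_bank(z)
  expect_true(all(vapply(dz, function(tr) max(tr$y), 0) == 0))
  # group 3 bursts at stance onset, group 4 at stance end
  onset2 <- attr(rec, "onsets")[2]; offset2 <- attr(rec, "offsets")[2]
  t <- d[["3"]]$t
  t3_peak <- t[t >= onset2 - 1 & t <= onset2 + 1][
    which.max(d[["3"]]$y[t >= onset2 - 1 & t <= onset2 + 1])]
  expect_lt(abs(t3_peak - onset2), 0.3)
  t4_peak <- t[t >= offset2 - 1 & t <= offset2 + 1][
    which.max(d[["4"]]$y[t >= offset2 - 1 & t <= offset2 + 1])]
  expect_lt(abs(t4_peak - offset2), 0.3)
  # missing channel is a configuration error
  expect_error(group_bank(z[, -3]), "channel")
})
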