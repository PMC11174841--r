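test_that("profile interpolates all 13 knots and carries the requested peaks", {
  pr <- build_profile(17.5, -17.5)
  expect_identical(nrow(pr$knots), 13L)
  expect_lt(max(abs(evaluate_profile(pr, pr$knots$phase_pct) -
                      pr$knots$torque_nm)), 1e-9)

  # cycle extrema: attained at the peak knots, magnitude within the cubic
  # between-knot bulge (< 1e-3 Nm)
  ph <- seq(0, 100, by = 0.02)
  v <- evaluate_profile(pr, ph)
  expect_equal(max(v), 17.5, tolerance = 1e-3)
  expect_equal(min(v), -17.5, tolerance = 1e-3)
  expect_lt(abs(ph[which.max(v)] - 62), 0.5)
  expect_lt(abs(ph[which.min(v)] - 88), 0.5)

  # zero-torque plateau while the leg is stretched: residual spline ripple
  # stays below 1% of the peak
  expect_lt(max(abs(evaluate_profile(pr, seq(0, 38, by = 0.5)))),
            0.01 * 17.5)

  # all-zero template -> identically zero profile
  tpl0 <- default_knot_template()
  tpl0$flexion_scale <- tpl0$extension_scale <- 0
  expect_equal(max(abs(evaluate_profile(build_profile(17.5, -17.5, tpl0),
                                        ph))), 0)

  # out-of-box peaks are clamped with a warning
  expect_warning(pr2 <- build_profile(25, -17.5), "clamping")
  expect_equal(pr2$flexion_peak, 20)
  expect_error(build_profile(17, -17,
                             template = data.frame(phase_pct = c(0, 50, 50),
                                                   flexion_scale = 0,
                                                   extension_scale = 0)),
               "strictly increasing")
})

test_that("spline matches the independent natural-spline oracle on random knots", {
  set.seed(21)
  for (i in 1:15) {
    phases <- sort(runif(13, 0, 100))
    while (min(diff(phases)) < 1) phases <- sort(runif(13, 0, 100))
    torques <- rnorm(13, 0, 8)
    tpl <- data.frame(phase_pct = phases, flexion_scale = 0,
                      extension_scale = 0)
    pr <- build_profile(0, 0, template = tpl)
    pr$knots$torque_nm <- torques
    cf <- exohitl:::natural_spline_coefs(phases, torques)
    pr$a <- cf$a; pr$b <- cf$b; pr$c <- cf$c
    xs <- seq(min(phases), max(phases), length.out = 400)
    mine <- evaluate_profile(pr, xs)
    oracle <- spline(phases, torques, xout = xs, method = "natural")$y
    expect_lt(max(abs(mine - oracle)), 1e-10)
  }
})

test_that("natural boundary conditions: zero second derivative at both ends", {
  pr <- build_profile(18, -17.9)
  # T''(p) on segment i is 2 b_i + 6 c_i (p - p_i): exactly zero at both ends
  expect_equal(2 * pr$b[1], 0)
  h_last <- diff(tail(pr$knots$phase_pct, 2))
  expect_equal(2 * pr$b[12] + 6 * pr$c[12] * h_last, 0, tolerance = 1e-10)
  # corroborated by finite differences (one-sided stencils carry O(h) error
  # from the nonzero third derivative, hence the looser tolerance)
  h <- 1e-4
  d2 <- function(p) (evaluate_profile(pr, p + h) - 2 * evaluate_profile(pr, p) +
                       evaluate_profile(pr, p - h)) / h^2
  expect_lt(abs(d2(0 + h)), 1e-3)
  expect_lt(abs(d2(100 - h)), 1e-3)
  # C2 continuity at an interior knot: curvature matches across the joint
  expect_lt(abs(d2(62 - 2 * h) - d2(62 + 2 * h)), 1e-2)
  expect_error(evaluate_profile(pr, 101), "phase")
})

test_that("gait phase advances linearly and wraps without drift", {
  st <- gait_state(cycle_duration = 2, tick = 0.010)
  st1 <- advance_phase(st)
  expect_equal(st1$phase, 0.5)
  # 200 ticks = one full cycle back to the start
  for (i in 1:199) st1 <- advance_phase(st1)
  expect_equal(st1$phase, 0, tolerance = 1e-9)

  st2 <- gait_state(cycle_duration = 2, tick = 0.010, phase = 99.8)
  expect_equal(advance_phase(st2)$phase, 0.3, tolerance = 1e-9)

  # no drift across many cycles (distance to the wrap point)
  stl <- gait_state(cycle_duration = 2.2, tick = 0.010)
  n_cycles <- 500
  for (i in seq_len(n_cycles * 220)) stl <- advance_phase(stl)
  expect_lt(min(stl$phase, 100 - stl$phase), 1e-6)

  # speed -> duration lookup hits the configured table entry
  expect_equal(speed_to_cycle_duration(1.5), 2.2)
  expect_error(speed_to_cycle_duration(5), "outside")
})

test_that("PID arithmetic and closed-loop tracking", {
  g <- pid_gains() # 135, 1.5, 1.5 at 1 kHz
  # zero error, zero history -> zero command
  expect_equal(pid_step(g, 0, 0)$command, 0)
  # constant error 1, P-only -> command 135
  gp <- pid_gains(kp = 135, ki = 0, kd = 0)
  st <- pid_state(); st$prev_error <- 1 # steady error, no derivative kick
  expect_equal(pid_step(gp, 1, 0, st)$command, 135)

  # step reference into the first-order plant: |error| < 2% after 0.5 s
  tpl_const <- default_knot_template()
  tpl_const$flexion_scale <- 0.25 # constant 5 Nm reference at peak 20
  tpl_const$extension_scale <- 0
  pr_const <- build_profile(20, -15, template = tpl_const)
  tr <- simulate_tracking(pr_const, gait_state(speed_kmh = 1.5), g,
                          motor_plant(), duration = 2)
  after <- tr$trace[tr$trace$time_s >= 0.5, ]
  expect_lt(max(abs(after$measured_nm - 5)), 0.02 * 5)
  # steady state: < 1% at the end of the bout
  expect_lt(abs(tail(tr$trace$measured_nm, 1) - 5), 0.01 * 5)
})

test_that("zero-torque mode keeps the measured torque at zero", {
  tr <- simulate_tracking(build_profile(0, 0), gait_state(speed_kmh = 1.5),
                          pid_gains(), motor_plant(), duration = 3)
  expect_lt(max(abs(tr$trace$measured_nm)), 1e-9)
  expect_equal(tr$rms_error, 0, tolerance = 1e-12)
})

test_that("tracking improves with gain and commands respect saturation", {
  pr <- build_profile(18, -17.9)
  g_hi <- pid_gains(kp = 135, ki = 1.5, kd = 1.5)
  g_lo <- pid_gains(kp = 13.5, ki = 1.5, kd = 1.5)
  t_hi <- simulate_tracking(pr, gait_state(speed_kmh = 1.5), g_hi,
                            motor_plant(), duration = 3)
  t_lo <- simulate_tracking(pr, gait_state(speed_kmh = 1.5), g_lo,
                            motor_plant(), duration = 3)
  expect_lt(t_hi$rms_error, t_lo$rms_error)
  expect_true(all(abs(t_hi$trace$command_nm) <= 20 + 1e-9))
  expect_true(all(abs(t_hi$trace$measured_nm) <= 20 + 1e-9))
})
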