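# Reference torque-profile generation (13-knot natural cubic spline over the
# gait cycle), gait-phase advancement, and PID torque tracking against a
# first-order actuator plant.

#' Default 13-knot torque-profile template
#'
#' Knot phases (percent of gait cycle) and per-knot scale factors applied to
#' the flexion peak (positive scales) or extension peak (negative column).
#' The shape follows the assisted knee cycle: a zero-torque plateau while the
#' leg is stretched (stance), one positive lobe driving knee flexion, then one
#' negative lobe driving extension. Knot 6 carries the flexion peak, knot 10
#' the extension peak; zero anchors enforce the flat segment. The exact knot
#' placement is a package choice (the published figure is not tabulated) and
#' is fully configurable.
#'
#' @return Data frame with columns `phase_pct`, `flexion_scale`,
#'   `extension_scale` (13 rows).
#' @export
default_knot_template <- function() {
  data.frame(
    phase_pct       = c(0, 12, 25, 38, 48, 55, 62, 69, 76, 82, 88, 94, 100),
    flexion_scale   = c(0, 0, 0, 0, 0, 0.30, 1, 0.30, 0, 0, 0, 0, 0),
    extension_scale = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0.30, 1, 0.30, 0))
}

# Natural cubic spline through (x, y): returns per-segment coefficients
# (a, b, c) such that on [x_i, x_{i+1}]
#   T(P) = y_i + a_i (P - x_i) + b_i (P - x_i)^2 + c_i (P - x_i)^3,
# with zero second derivative at both ends. Interior second derivatives come
# from the standard tridiagonal system, solved by the Thomas algorithm.
natural_spline_coefs <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (any(diff(x) <= 0)) stop("knot phases must be strictly increasing")
  h <- diff(x)
  # tridiagonal system for M_2..M_{n-1} (M_1 = M_n = 0)
  m <- n - 2L
  lower <- upper <- if (m >= 2L) h[2:(n - 2)] else numeric(0)
  diag_ <- 2 * (h[1:(n - 2)] + h[2:(n - 1)])
  rhs <- 6 * ((y[3:n] - y[2:(n - 1)]) / h[2:(n - 1)] -
                (y[2:(n - 1)] - y[1:(n - 2)]) / h[1:(n - 2)])
  # Thomas algorithm
  if (m == 1L) {
    M_int <- rhs / diag_
  } else {
    cp <- numeric(m); dp <- numeric(m)
    cp[1] <- upper[1] / diag_[1]
    dp[1] <- rhs[1] / diag_[1]
    for (i in 2:m) {
      denom <- diag_[i] - lower[i - 1] * cp[i - 1]
      cp[i] <- if (i < m) upper[i] / denom else 0
      dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
    }
    M_int <- numeric(m)
    M_int[m] <- dp[m]
    for (i in (m - 1):1) M_int[i] <- dp[i] - cp[i] * M_int[i + 1]
  }
  M <- c(0, M_int, 0)
  i <- 1:(n - 1)
  a <- (y[i + 1] - y[i]) / h - h * (2 * M[i] + M[i + 1]) / 6
  b <- M[i] / 2
  c <- (M[i + 1] - M[i]) / (6 * h)
  list(a = a, b = b, c = c, M = M)
}

#' Build a knee torque profile from flexion/extension peaks
#'
#' Scales the knot template by the requested peaks and interpolates the 13
#' knots with a natural cubic spline (zero second derivative at both ends),
#' storing the per-segment coefficient arrays (a, b, c).
#'
#' Peaks outside the optimizer's bounds (flexion in \[15, 20\] Nm, extension
#' in \[-20, -15\] Nm) are clamped with a warning; zero peaks are accepted
#' silently (transparent / zero-torque mode).
#'
#' @param flexion_peak flexion torque peak in Nm (positive).
#' @param extension_peak extension torque peak in Nm (negative).
#' @param template knot template as from [default_knot_template()].
#' @param bounds list with `flexion = c(lo, hi)`, `extension = c(lo, hi)` used
#'   for the soft clamp (defaults to the optimizer's box).
#' @return Object of class `torque_profile` with `knots` (13 x 2), spline
#'   coefficients, and the peaks; evaluate with [predict.torque_profile()] or
#'   [evaluate_profile()].
#' @export
build_profile <- function(flexion_peak, extension_peak,
                          template = default_knot_template(),
                          bounds = list(flexion = c(15, 20),
                                        extension = c(-20, -15))) {
  stopifnot(is.data.frame(template),
            all(c("phase_pct", "flexion_scale", "extension_scale") %in%
                  names(template)))
  if (any(diff(template$phase_pct) <= 0))
    stop("invalid template: knot phases must be strictly increasing")
  zero_mode <- flexion_peak == 0 && extension_peak == 0
  if (!zero_mode) {
    if (flexion_peak < bounds$flexion[1] || flexion_peak > bounds$flexion[2]) {
      warning("flexion peak ", flexion_peak, " outside [",
              bounds$flexion[1], ", ", bounds$flexion[2], "] Nm; clamping")
      flexion_peak <- clamp(flexion_peak, bounds$flexion[1], bounds$flexion[2])
    }
    if (extension_peak < bounds$extension[1] ||
        extension_peak > bounds$extension[2]) {
      warning("extension peak ", extension_peak, " outside [",
              bounds$extension[1], ", ", bounds$extension[2],
              "] Nm; clamping")
      extension_peak <- clamp(extension_peak, bounds$extension[1],
                              bounds$extension[2])
    }
  }
  torque <- template$flexion_scale * flexion_peak +
    template$extension_scale * extension_peak
  coefs <- natural_spline_coefs(template$phase_pct, torque)
  structure(list(knots = data.frame(phase_pct = template$phase_pct,
                                    torque_nm = torque),
                 a = coefs$a, b = coefs$b, c = coefs$c, M = coefs$M,
                 flexion_peak = flexion_peak,
                 extension_peak = extension_peak),
            class = "torque_profile")
}

#' Evaluate a torque profile at gait phases
#'
#' Piecewise-cubic evaluation: for segment `i` with
#' \eqn{p_i \le P < p_{i+1}},
#' \eqn{T(P) = t_i + a_i (P-p_i) + b_i (P-p_i)^2 + c_i (P-p_i)^3}.
#'
#' @param profile a [build_profile()] object.
#' @param phase gait phase(s) in percent, each in \[0, 100\].
#' @return Torque in Nm (vectorized over `phase`).
#' @export
evaluate_profile <- function(profile, phase) {
  stopifnot(inherits(profile, "torque_profile"))
  if (any(phase < 0 | phase > 100))
    stop("phase must lie in [0, 100]")
  p <- profile$knots$phase_pct
  t <- profile$knots$torque_nm
  idx <- findInterval(phase, p, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  d <- phase - p[idx]
  t[idx] + profile$a[idx] * d + profile$b[idx] * d^2 + profile$c[idx] * d^3
}

#' @rdname evaluate_profile
#' @param object a `torque_profile`.
#' @param ... unused.
#' @export
predict.torque_profile <- function(object, phase, ...) {
  evaluate_profile(object, phase)
}

#' @export
print.torque_profile <- function(x, ...) {
  cat(sprintf("<torque_profile> 13 knots, flexion peak %.2f Nm, extension peak %.2f Nm\n",
              x$flexion_peak, x$extension_peak))
  invisible(x)
}

#' @export
plot.torque_profile <- function(x, n = 400, ...) {
  ph <- seq(0, 100, length.out = n)
  graphics::plot(ph, evaluate_profile(x, ph), type = "l",
                 xlab = "Gait cycle (%)", ylab = "Torque (Nm)", ...)
  graphics::points(x$knots$phase_pct, x$knots$torque_nm, pch = 19)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Export / import a torque profile as CSV
#'
#' 13 knot rows (`phase_pct`, `torque_nm`); peaks stored as comment-free extra
#' columns on the first row.
#' @param profile a `torque_profile`.
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  d <- profile$knots
  d$flexion_peak_nm <- c(profile$flexion_peak, rep(NA, nrow(d) - 1L))
  d$extension_peak_nm <- c(profile$extension_peak, rep(NA, nrow(d) - 1L))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# ---- gait phase ------------------------------------------------------------

#' Map gait speed to cycle duration
#'
#' Piecewise-linear lookup over the exoskeleton's supported speed range
#' (0.5-1.6 km/h). The anchors are a package choice for slow treadmill gait:
#' 3.2 s at 0.5 km/h down to 2.1 s at 1.6 km/h (2.2 s at the 1.5 km/h
#' condition used throughout).
#'
#' @param speed_kmh gait speed in km/h.
#' @param table optional replacement lookup (data frame with `speed_kmh`,
#'   `cycle_s`).
#' @return Cycle duration in seconds.
#' @export
speed_to_cycle_duration <- function(speed_kmh,
                                    table = data.frame(
                                      speed_kmh = c(0.5, 0.8, 1.0, 1.2, 1.5, 1.6),
                                      cycle_s = c(3.2, 2.9, 2.7, 2.45, 2.2, 2.1))) {
  if (speed_kmh < min(table$speed_kmh) || speed_kmh > max(table$speed_kmh))
    stop("speed ", speed_kmh, " km/h outside supported range [",
         min(table$speed_kmh), ", ", max(table$speed_kmh), "]")
  stats::approx(table$speed_kmh, table$cycle_s, xout = speed_kmh)$y
}

#' Gait-phase modulator state
#'
#' Free-running linear phase advance: every `tick` seconds the phase grows by
#' `100 * tick / cycle_duration` percent, wrapping at 100.
#'
#' @param speed_kmh gait speed (used to infer `cycle_duration`), or supply
#'   `cycle_duration` directly.
#' @param cycle_duration gait-cycle duration in seconds.
#' @param tick mid-level control period in seconds (default 0.010).
#' @param phase initial phase in percent (default 0).
#' @return Object of class `gait_state`.
#' @export
gait_state <- function(speed_kmh = NULL, cycle_duration = NULL, tick = 0.010,
                       phase = 0) {
  if (is.null(cycle_duration)) {
    if (is.null(speed_kmh)) stop("need speed_kmh or cycle_duration")
    cycle_duration <- speed_to_cycle_duration(speed_kmh)
  }
  stopifnot(cycle_duration > 0, tick > 0, phase >= 0, phase < 100)
  structure(list(phase = phase, cycle_duration = cycle_duration, tick = tick),
            class = "gait_state")
}

#' Advance the gait phase by one mid-level tick
#'
#' @param state a [gait_state()].
#' @return Updated state with `phase` incremented by
#'   `100 * tick / cycle_duration`, wrapped modulo 100.
#' @export
advance_phase <- function(state) {
  state$phase <- (state$phase + 100 * state$tick / state$cycle_duration) %% 100
  state
}

# ---- PID + plant -----------------------------------------------------------

#' PID controller gains
#'
#' Defaults are the published knee-exoskeleton gains (kp 135, ki 1.5, kd 1.5)
#' with a 1 kHz control loop. The derivative term is low-pass filtered
#' (first-order, time constant `deriv_filter`); an unfiltered
#' backward-difference derivative at 1 kHz would multiply per-sample error
#' changes by `kd / loop_period` = 1500 and destabilize the discrete loop.
#'
#' @param kp,ki,kd non-negative gains.
#' @param loop_period control period in seconds (default 0.001).
#' @param deriv_filter derivative low-pass time constant in seconds (default
#'   0.05; 0 disables filtering).
#' @export
pid_gains <- function(kp = 135, ki = 1.5, kd = 1.5, loop_period = 0.001,
                      deriv_filter = 0.05) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, loop_period > 0, deriv_filter >= 0)
  structure(list(kp = kp, ki = ki, kd = kd, loop_period = loop_period,
                 deriv_filter = deriv_filter),
            class = "pid_gains")
}

#' One PID step
#'
#' Discrete PID with trapezoidal integrator, low-pass-filtered
#' backward-difference derivative on the error, and anti-windup by clamping
#' the integrator when the command saturates at `command_limit`.
#'
#' @param gains a [pid_gains()].
#' @param reference desired torque (Nm).
#' @param measured measured torque (Nm).
#' @param state controller state: list with `integral`, `prev_error`,
#'   `deriv` (use [pid_state()] for a fresh one).
#' @param command_limit symmetric saturation for the command (Nm; `Inf` to
#'   disable).
#' @return List with `command` and the updated `state`.
#' @export
pid_step <- function(gains, reference, measured, state = pid_state(),
                     command_limit = Inf) {
  e <- reference - measured
  dt <- gains$loop_period
  integral <- state$integral + 0.5 * (e + state$prev_error) * dt
  beta <- gains$deriv_filter / (gains$deriv_filter + dt)
  deriv <- beta * state$deriv + (1 - beta) * (e - state$prev_error) / dt
  u <- gains$kp * e + gains$ki * integral + gains$kd * deriv
  if (abs(u) > command_limit) {
    u_sat <- sign(u) * command_limit
    # anti-windup: keep the integrator where it was when saturating further
    if (gains$ki > 0 && sign(e) == sign(u)) integral <- state$integral
    u <- u_sat
  }
  list(command = u,
       state = list(integral = integral, prev_error = e, deriv = deriv))
}

#' @rdname pid_step
#' @export
pid_state <- function() list(integral = 0, prev_error = 0, deriv = 0)

#' First-order actuator plant
#'
#' Motor torque responds to the command with a first-order lag (exact
#' discretization), saturates at `torque_limit`, and optionally carries
#' Gaussian measurement noise. The lag model and noise are simulation
#' plumbing; the torque limit matches the actuator's 20 Nm nominal torque.
#'
#' @param torque_limit symmetric torque saturation in Nm (default 20).
#' @param time_constant actuator lag in seconds (default 0.1; with the
#'   published kp = 135 the 1 kHz discrete loop is only stable for lags of
#'   roughly 0.07 s and above).
#' @param noise_sd measurement noise SD in Nm (default 0).
#' @param torque initial torque (default 0).
#' @export
motor_plant <- function(torque_limit = 20, time_constant = 0.1,
                        noise_sd = 0, torque = 0) {
  stopifnot(torque_limit > 0, time_constant > 0, noise_sd >= 0)
  structure(list(torque_limit = torque_limit, time_constant = time_constant,
                 noise_sd = noise_sd, torque = torque),
            class = "motor_plant")
}

# One plant step at dt seconds: exact first-order response to a held command.
plant_step <- function(plant, command, dt) {
  a <- 1 - exp(-dt / plant$time_constant)
  tau <- plant$torque + a * (command - plant$torque)
  tau <- clamp(tau, -plant$torque_limit, plant$torque_limit)
  if (!is.finite(tau)) stop("plant divergence: torque is not finite")
  plant$torque <- tau
  measured <- tau + if (plant$noise_sd > 0) stats::rnorm(1, 0, plant$noise_sd)
                    else 0
  list(plant = plant, measured = measured)
}

#' Simulate closed-loop torque tracking over a walking bout
#'
#' Nested control loops as in the real system: the gait phase and the
#' reference torque update every `gait$tick` (10 ms by default, the mid-level
#' period); the PID controller and the actuator plant run every
#' `gains$loop_period` (1 ms by default). Commands saturate at the plant's
#' torque limit.
#'
#' @param profile a [build_profile()] torque profile.
#' @param gait a [gait_state()].
#' @param gains a [pid_gains()].
#' @param plant a [motor_plant()].
#' @param duration simulated time in seconds.
#' @return Object of class `tracking_trace`: data frame `trace` (time_s,
#'   phase_pct, reference_nm, measured_nm, command_nm) thinned to the
#'   mid-level rate, plus `rms_error` (Nm, over all low-level steps).
#' @export
simulate_tracking <- function(profile, gait, gains, plant, duration) {
  stopifnot(duration > 0)
  n_mid <- ceiling(duration / gait$tick)
  per_mid <- max(1L, round(gait$tick / gains$loop_period))
  pid <- pid_state()
  sq_err <- 0; n_ll <- 0L
  out_time <- out_phase <- out_ref <- out_meas <- out_cmd <- numeric(n_mid)
  t_now <- 0
  for (k in seq_len(n_mid)) {
    reference <- evaluate_profile(profile, gait$phase)
    meas_k <- cmd_k <- NA_real_
    for (j in seq_len(per_mid)) {
      measured <- plant$torque
      st <- pid_step(gains, reference, measured, pid,
                     command_limit = plant$torque_limit)
      pid <- st$state
      ps <- plant_step(plant, st$command, gains$loop_period)
      plant <- ps$plant
      sq_err <- sq_err + (reference - ps$measured)^2
      n_ll <- n_ll + 1L
      meas_k <- ps$measured; cmd_k <- st$command
    }
    out_time[k] <- t_now; out_phase[k] <- gait$phase
    out_ref[k] <- reference; out_meas[k] <- meas_k; out_cmd[k] <- cmd_k
    gait <- advance_phase(gait)
    t_now <- t_now + gait$tick
  }
  structure(list(trace = data.frame(time_s = out_time, phase_pct = out_phase,
                                    reference_nm = out_ref,
                                    measured_nm = out_meas,
                                    command_nm = out_cmd),
                 rms_error = sqrt(sq_err / n_ll),
                 final_plant = plant),
            class = "tracking_trace")
}

#' @export
print.tracking_trace <- function(x, ...) {
  cat(sprintf("<tracking_trace> %d mid-level steps, RMS tracking error %.4g Nm\n",
              nrow(x$trace), x$rms_error))
  invisible(x)
}

#' @export
plot.tracking_trace <- function(x, ...) {
  graphics::plot(x$trace$time_s, x$trace$reference_nm, type = "l",
                 xlab = "Time (s)", ylab = "Torque (Nm)", ...)
  graphics::lines(x$trace$time_s, x$trace$measured_nm, col = "red")
  graphics::legend("topright", legend = c("reference", "measured"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}
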