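# Synthetic walker closing the HITL loop: emits gait-locked accelerometry, a
# metabolic-cost response and an interaction-torque response as functions of
# the applied torque peaks. The functional forms are deliberately simple —
# a convex quadratic metabolic bowl and a linearly decreasing interaction
# torque — the simplest shapes consistent with the qualitative mechanism that
# higher torque peaks speed up the movement (raising metabolic cost) while
# lower peaks leave more work to the user (raising interaction torque). The
# default surfaces place the unit-weight cost-function minimum at
# (18.0, -17.9) Nm as a familiar reference optimum for recovery experiments,
# not as a claim of physiological fidelity.

#' Configure a synthetic exoskeleton user
#'
#' Ground-truth response surfaces over the torque-peak box
#' \[15, 20\] x \[-20, -15\] Nm:
#' \deqn{mc(f, e) = mc_0 + \alpha_f (f - f^\circ)^2 + \alpha_e (e - e^\circ)^2}
#' (W/kg, convex with vertex \eqn{(f^\circ, e^\circ)}), and
#' \deqn{it(f, e) = \max(it_{min},\; it_0 - \beta_f (f - 15) - \beta_e (|e| - 15))}
#' (Nm, decreasing in assistance). With the defaults the noise-free combined
#' cost \eqn{mc + it} has its unique interior minimum at exactly
#' (18.0, -17.9) Nm.
#'
#' Separate anchors define the non-optimized conditions: `mc_zero_torque` /
#' `it_zero_torque` (transparent mode: no assistance, baseline device
#' resistance) and `mc_no_device` (no exoskeleton, zero interaction torque).
#'
#' @param bmi subject body mass index in kg/m^2 (default 24.5).
#' @param gait_speed treadmill speed in km/h (default 1.5).
#' @param mc0 metabolic cost at the vertex (W/kg).
#' @param alpha_f,alpha_e metabolic curvature (W/kg per Nm^2).
#' @param vertex_f,vertex_e vertex of the metabolic bowl (Nm).
#' @param it0 interaction torque at minimal assistance (15, -15) (Nm).
#' @param beta_f,beta_e interaction-torque slopes (per Nm of extra peak).
#' @param it_min floor of the interaction torque (Nm).
#' @param noise_sd_mc SD of metabolic noise (W/kg) added to targets/true mc.
#' @param noise_sd_it SD of interaction-torque noise (Nm).
#' @param noise_sd_accel SD of accelerometer noise (m/s^2).
#' @param accel_gain scaling from metabolic cost to movement vigor
#'   (m/s^2 per W/kg) in the accelerometry model.
#' @param mc_zero_torque,it_zero_torque,mc_no_device condition anchors (see
#'   above).
#' @param check_optimum verify at construction (41 x 41 grid) that the
#'   unit-weight cost surface has a unique interior minimum; disable for
#'   deliberately degenerate configurations.
#' @return Object of class `synthetic_user`.
#' @export
synthetic_user <- function(bmi = 24.5, gait_speed = 1.5,
                           mc0 = 3.0, alpha_f = 0.15, alpha_e = 0.15,
                           vertex_f = 17.0, vertex_e = -16.9,
                           it0 = 3.0, beta_f = 0.30, beta_e = 0.30,
                           it_min = 0,
                           noise_sd_mc = 0.05, noise_sd_it = 0.05,
                           noise_sd_accel = 0.02, accel_gain = 0.3,
                           mc_zero_torque = 3.56, it_zero_torque = 1.82,
                           mc_no_device = 3.51,
                           check_optimum = TRUE) {
  stopifnot(alpha_f >= 0, alpha_e >= 0, beta_f >= 0, beta_e >= 0,
            it_min >= 0, noise_sd_mc >= 0, noise_sd_it >= 0,
            noise_sd_accel >= 0, bmi > 0)
  user <- structure(
    list(bmi = bmi, gait_speed = gait_speed,
         mc0 = mc0, alpha_f = alpha_f, alpha_e = alpha_e,
         vertex_f = vertex_f, vertex_e = vertex_e,
         it0 = it0, beta_f = beta_f, beta_e = beta_e, it_min = it_min,
         noise_sd_mc = noise_sd_mc, noise_sd_it = noise_sd_it,
         noise_sd_accel = noise_sd_accel, accel_gain = accel_gain,
         mc_zero_torque = mc_zero_torque, it_zero_torque = it_zero_torque,
         mc_no_device = mc_no_device,
         bounds = list(flexion = c(15, 20), extension = c(-20, -15))),
    class = "synthetic_user")
  if (check_optimum && (alpha_f > 0 || alpha_e > 0)) {
    surf <- true_cost_surface(user, resolution = 41)
    am <- surf$argmin
    eps <- diff(user$bounds$flexion) / 40
    interior <- am[1] > 15 + eps / 2 && am[1] < 20 - eps / 2 &&
      am[2] > -20 + eps / 2 && am[2] < -15 - eps / 2
    if (!interior)
      warning("configured cost surface has no interior minimum on the box; ",
              "recovery experiments will push against the bounds")
  }
  user
}

#' @export
print.synthetic_user <- function(x, ...) {
  cat(sprintf("<synthetic_user> BMI %.1f, %.1f km/h\n", x$bmi, x$gait_speed))
  cat(sprintf("  mc(f,e) = %.2f + %.2f(f-%.1f)^2 + %.2f(e-(%.1f))^2 W/kg\n",
              x$mc0, x$alpha_f, x$vertex_f, x$alpha_e, x$vertex_e))
  cat(sprintf("  it(f,e) = max(%.1f, %.2f - %.2f(f-15) - %.2f(|e|-15)) Nm\n",
              x$it_min, x$it0, x$beta_f, x$beta_e))
  cat(sprintf("  noise SD: mc %.3g W/kg, it %.3g Nm, accel %.3g m/s^2\n",
              x$noise_sd_mc, x$noise_sd_it, x$noise_sd_accel))
  invisible(x)
}

# Noise-free surfaces.
true_mc <- function(user, flexion, extension) {
  user$mc0 + user$alpha_f * (flexion - user$vertex_f)^2 +
    user$alpha_e * (extension - user$vertex_e)^2
}

true_it <- function(user, flexion, extension) {
  pmax(user$it_min,
       user$it0 - user$beta_f * (flexion - 15) -
         user$beta_e * (abs(extension) - 15))
}

in_peak_bounds <- function(user, flexion, extension) {
  flexion >= user$bounds$flexion[1] && flexion <= user$bounds$flexion[2] &&
    extension >= user$bounds$extension[1] &&
    extension <= user$bounds$extension[2]
}

#' Simulate one walking bout under given torque peaks
#'
#' Produces the three signals one HITL iteration consumes: (i) a 4-site,
#' 12-channel acceleration stream whose per-site sinusoidal amplitudes scale
#' with the (noise-free) metabolic cost, so MAD features carry metabolic
#' information; (ii) an interaction-torque series (rectified
#' surface-value-plus-noise at 100 Hz); (iii) the noise-free `true_mc`, for
#' oracle use only — never exposed to the optimizer path.
#'
#' @param user a [synthetic_user()].
#' @param flexion_peak,extension_peak applied torque peaks (Nm), inside the
#'   optimizer's box.
#' @param duration bout duration in seconds (default 10).
#' @param rate sampling rate in Hz (default 100).
#' @param seed optional seed for a private RNG stream (reproducible bouts);
#'   if `NULL` the current RNG stream is consumed.
#' @return Object of class `simulated_bout`: `accel` ([accel_stream]),
#'   `it_series` (Nm, rectified), `true_mc` (W/kg), `mc_observed` (true_mc +
#'   metabolic noise).
#' @export
simulate_bout <- function(user, flexion_peak, extension_peak, duration = 10,
                          rate = 100, seed = NULL) {
  stopifnot(inherits(user, "synthetic_user"), duration > 0)
  if (!in_peak_bounds(user, flexion_peak, extension_peak))
    stop("peaks (", flexion_peak, ", ", extension_peak,
         ") outside the torque-peak box")
  mc <- true_mc(user, flexion_peak, extension_peak)
  it_level <- true_it(user, flexion_peak, extension_peak)
  run <- function() {
    bout <- bout_from_levels(user, mc, it_level, duration, rate)
    bout$flexion_peak <- flexion_peak
    bout$extension_peak <- extension_peak
    bout
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Gait-locked accelerometry + interaction-torque series for given noise-free
# metabolic and interaction-torque levels. Shared by the torque-driven bouts
# and the non-assisted conditions (zero-torque, no-device).
bout_from_levels <- function(user, mc, it_level, duration = 10, rate = 100) {
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  f0 <- 1 / speed_to_cycle_duration(user$gait_speed)  # stride frequency
  # per-channel amplitude scale and harmonic: ankle moves most, chest least
  site_scale <- rep(c(chest = 0.25, wrist = 0.5, waist = 0.35,
                      ankle = 1.0), each = 3)
  axis_mult <- rep(c(1, 0.7, 0.5), times = 4)
  harmonic <- rep(c(1, 1, 1, 2), each = 3)  # ankle locked at 2x stride
  phase_off <- seq(0, 2 * pi, length.out = 13)[1:12]
  amp <- user$accel_gain * mc * site_scale * axis_mult
  acc <- sapply(1:12, function(j)
    amp[j] * sin(2 * pi * harmonic[j] * f0 * tt + phase_off[j]))
  if (user$noise_sd_accel > 0)
    acc <- acc + matrix(stats::rnorm(n * 12, 0, user$noise_sd_accel), n, 12)
  it_series <- abs(it_level +
                     if (user$noise_sd_it > 0)
                       stats::rnorm(n, 0, user$noise_sd_it) else 0)
  mc_observed <- mc + if (user$noise_sd_mc > 0)
    stats::rnorm(1, 0, user$noise_sd_mc) else 0
  structure(list(accel = accel_stream(acc, rate), it_series = it_series,
                 true_mc = mc, mc_observed = mc_observed,
                 flexion_peak = NA_real_, extension_peak = NA_real_),
            class = "simulated_bout")
}

#' @export
print.simulated_bout <- function(x, ...) {
  cat(sprintf("<simulated_bout> peaks (%.2f, %.2f) Nm, %.0f s, true mc %.3f W/kg\n",
              x$flexion_peak, x$extension_peak,
              nrow(x$accel$data) / x$accel$rate, x$true_mc))
  invisible(x)
}

#' Build a grouped training set for the estimator
#'
#' Simulates bouts for every subject x grid-point x repetition, runs the full
#' preprocessing pipeline (filter, window, MAD features, BMI), and pairs the
#' feature vectors with noisy metabolic-cost targets. Subjects differ by BMI
#' and by small jitter on the surface coefficients, giving non-trivial
#' leave-one-subject-out folds.
#'
#' @param user a [synthetic_user()] serving as the base configuration.
#' @param grid data frame with columns `flexion`, `extension` (defaults to a
#'   5 x 5 grid over the box).
#' @param reps repetitions per grid point (default 1).
#' @param n_subjects number of synthetic subjects (default 3). BMIs are spread
#'   over 24-29 kg/m^2 (the range of the study population).
#' @param subject_jitter relative SD of per-subject surface-coefficient
#'   variation (default 0.05).
#' @param seed RNG seed for the private stream.
#' @return List: `features` (raw feature matrix, one row per bout window),
#'   `targets` (W/kg), `subjects` (id per row), `true_mc`, `peaks`,
#'   `subject_users` (the per-subject configurations).
#' @export
make_training_set <- function(user, grid = peak_grid(5), reps = 1,
                              n_subjects = 3, subject_jitter = 0.05,
                              seed = 1L) {
  stopifnot(nrow(grid) >= 1, reps >= 1, n_subjects >= 1)
  with_seed(seed, {
    bmis <- seq(24, 29, length.out = max(n_subjects, 2))[seq_len(n_subjects)]
    subject_users <- lapply(seq_len(n_subjects), function(s) {
      u <- user
      u$bmi <- bmis[s]
      jit <- function(v) v * (1 + subject_jitter * stats::rnorm(1))
      u$mc0 <- jit(u$mc0); u$alpha_f <- jit(u$alpha_f)
      u$alpha_e <- jit(u$alpha_e); u$it0 <- jit(u$it0)
      u
    })
    rows <- list(); k <- 0L
    for (s in seq_len(n_subjects)) {
      us <- subject_users[[s]]
      for (i in seq_len(nrow(grid))) for (r in seq_len(reps)) {
        bout <- simulate_bout(us, grid$flexion[i], grid$extension[i])
        feats <- preprocess_stream(bout$accel, us$bmi)
        k <- k + 1L
        rows[[k]] <- list(f = feats[1, ], y = bout$mc_observed,
                          s = paste0("S", s), tm = bout$true_mc,
                          fl = grid$flexion[i], ex = grid$extension[i])
      }
    }
    list(features = do.call(rbind, lapply(rows, `[[`, "f")),
         targets = vapply(rows, `[[`, numeric(1), "y"),
         subjects = vapply(rows, `[[`, character(1), "s"),
         true_mc = vapply(rows, `[[`, numeric(1), "tm"),
         peaks = data.frame(flexion = vapply(rows, `[[`, numeric(1), "fl"),
                            extension = vapply(rows, `[[`, numeric(1), "ex")),
         subject_users = subject_users)
  })
}

#' Regular grid over the torque-peak box
#'
#' @param n_per_axis points per axis (>= 2).
#' @param bounds the peak box (defaults to the optimizer's).
#' @return Data frame with columns `flexion`, `extension`.
#' @export
peak_grid <- function(n_per_axis = 5,
                      bounds = list(flexion = c(15, 20),
                                    extension = c(-20, -15))) {
  stopifnot(n_per_axis >= 2)
  expand.grid(flexion = seq(bounds$flexion[1], bounds$flexion[2],
                            length.out = n_per_axis),
              extension = seq(bounds$extension[1], bounds$extension[2],
                              length.out = n_per_axis))
}

#' Noise-free combined-cost surface and its argmin
#'
#' Brute-force evaluation of `w1 * mc + w2 * it` over a regular grid on the
#' torque-peak box; the oracle for optimizer-recovery experiments.
#'
#' @param user a [synthetic_user()].
#' @param resolution grid points per axis (>= 2).
#' @param w1,w2 cost weights (default 1, 1).
#' @return List: `grid` (data frame flexion, extension, mc, it, cf), `argmin`
#'   (c(flexion, extension) of the first-minimum cell), `cf_min`.
#' @export
true_cost_surface <- function(user, resolution = 51, w1 = 1, w2 = 1) {
  stopifnot(resolution >= 2)
  g <- peak_grid(resolution, user$bounds)
  g$mc <- true_mc(user, g$flexion, g$extension)
  g$it <- true_it(user, g$flexion, g$extension)
  g$cf <- w1 * g$mc + w2 * g$it
  i <- which.min(g$cf)  # ties: first cell in grid order
  list(grid = g, argmin = c(flexion = g$flexion[i], extension = g$extension[i]),
       cf_min = g$cf[i])
}
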