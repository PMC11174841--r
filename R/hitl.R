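# Human-in-the-loop orchestration: per-iteration cost evaluation (estimated
# metabolic cost + collapsed interaction torque), CMA-ES scheduling, and the
# condition-comparison report.

#' Combined physical-effort cost function
#'
#' Weighted sum of the estimated metabolic cost and the collapsed interaction
#' torque: `w1 * mc + w2 * it`. The published system used equal unitary
#' weights; with the default interaction-torque reduction (mean absolute
#' torque, Nm) both terms sit within an order of magnitude of each other.
#'
#' @param mc estimated metabolic cost (W/kg), finite.
#' @param it collapsed interaction torque (Nm), finite and non-negative (a
#'   magnitude).
#' @param w1,w2 non-negative weights, not both zero (defaults 1, 1).
#' @return `w1 * mc + w2 * it`.
#' @export
cost_function <- function(mc, it, w1 = 1, w2 = 1) {
  if (w1 < 0 || w2 < 0 || (w1 == 0 && w2 == 0))
    stop("weights must be non-negative and not both zero")
  if (!all(is.finite(mc)) || !all(is.finite(it)))
    stop("cost_function: mc and it must be finite")
  if (any(it < 0))
    stop("interaction torque must be non-negative (it is a magnitude)")
  w1 * mc + w2 * it
}

#' Collapse an interaction-torque series over one iteration window
#'
#' Default `"mean_abs"`: mean of |torque| over the window (Nm). Alternative
#' `"cumulative"`: time integral of |torque| (Nm s), `sum(|tau|) * dt`.
#'
#' @param series torque samples (Nm) over one iteration window.
#' @param method `"mean_abs"` (default) or `"cumulative"`.
#' @param rate sampling rate in Hz (needed for `"cumulative"`; default 100).
#' @return Scalar collapsed torque.
#' @export
collapse_interaction_torque <- function(series,
                                        method = c("mean_abs", "cumulative"),
                                        rate = 100) {
  method <- match.arg(method)
  if (length(series) == 0L) stop("empty interaction-torque series")
  switch(method,
         mean_abs = mean(abs(series)),
         cumulative = sum(abs(series)) / rate)
}

#' Train the metabolic-cost estimator on synthetic data
#'
#' Convenience wrapper: builds a grouped training set from the synthetic user
#' ([make_training_set()]) and fits the EGPR ([egpr()]) on all of it.
#'
#' @param user a [synthetic_user()].
#' @param grid,reps,n_subjects,subject_jitter,seed see [make_training_set()].
#' @param ... passed to [egpr()].
#' @return A fitted [egpr] model (with the training set attached as
#'   `attr(, "training_set")`).
#' @export
train_estimator <- function(user, grid = peak_grid(5), reps = 2,
                            n_subjects = 3, subject_jitter = 0.05,
                            seed = 1L, ...) {
  ts <- make_training_set(user, grid, reps, n_subjects, subject_jitter, seed)
  model <- egpr(ts$features, ts$targets, ...)
  attr(model, "training_set") <- ts
  model
}

#' Run the full human-in-the-loop optimization in simulation
#'
#' Each iteration applies one candidate torque-peak pair to the synthetic
#' user, simulates a 10-s bout, estimates the metabolic cost from the bout's
#' accelerometry through the full preprocessing pipeline and the EGPR model,
#' collapses the interaction-torque series, combines both into the cost
#' function, and feeds the cost back to the CMA-ES. After the fixed
#' generation budget the optimum (final distribution mean, clamped) and the
#' complete per-iteration trace are returned.
#'
#' The optimizer sees only bout data (accelerometry and interaction torque);
#' the user's ground-truth surfaces are never consulted.
#'
#' @param user a [synthetic_user()].
#' @param model a fitted [egpr] metabolic-cost estimator.
#' @param config a [cmaes_config()] (default: the published schedule, 20
#'   generations x lambda 6).
#' @param w1,w2 cost-function weights (default 1, 1).
#' @param it_method interaction-torque reduction, see
#'   [collapse_interaction_torque()].
#' @param seed seed for the run's private RNG stream (drives both sampling
#'   and the simulated bouts).
#' @return Object of class `hitl_run`: `trace` (one row per iteration with
#'   peaks, mc, it, cost, best-so-far), `optimum`, `best_params`,
#'   `n_evaluations`, plus the underlying `cmaes_run`.
#' @export
run_hitl <- function(user, model, config = cmaes_config(), w1 = 1, w2 = 1,
                     it_method = "mean_abs", seed = 1L) {
  stopifnot(inherits(user, "synthetic_user"), inherits(model, "egpr"))
  log_env <- new.env(parent = emptyenv())
  log_env$mc <- log_env$it <- numeric(0)
  log_env$n <- 0L
  objective <- function(params) {
    bout <- simulate_bout(user, params[1], params[2])
    feats <- preprocess_stream(bout$accel, user$bmi)
    mc_hat <- predict(model, feats[1, ])
    it <- collapse_interaction_torque(bout$it_series, it_method,
                                      rate = bout$accel$rate)
    log_env$n <- log_env$n + 1L
    log_env$mc <- c(log_env$mc, mc_hat)
    log_env$it <- c(log_env$it, it)
    cost_function(mc_hat, it, w1, w2)
  }
  run <- cmaes_run(objective, config, seed)
  trace <- run$trace
  trace$mc_est_w_per_kg <- log_env$mc
  trace$it_nm <- log_env$it
  structure(list(trace = trace, optimum = run$optimum,
                 best_params = run$best_params, best_cost = run$best_cost,
                 n_evaluations = log_env$n, cmaes = run,
                 w1 = w1, w2 = w2, config = config, seed = seed),
            class = "hitl_run")
}

#' @export
print.hitl_run <- function(x, ...) {
  cat(sprintf("<hitl_run> %d iterations (%d generations x lambda=%d)\n",
              nrow(x$trace), x$config$generations, x$config$lam))
  cat(sprintf("  optimal peaks: flexion %.2f Nm, extension %.2f Nm\n",
              x$optimum[1], x$optimum[2]))
  cat(sprintf("  final-generation median cost %.3f (mc %.3f W/kg, it %.3f Nm)\n",
              stats::median(tail(x$trace$cost, x$config$lam)),
              stats::median(tail(x$trace$mc_est_w_per_kg, x$config$lam)),
              stats::median(tail(x$trace$it_nm, x$config$lam))))
  invisible(x)
}

#' @export
plot.hitl_run <- function(x, ...) plot(x$cmaes, ...)

#' Compare the optimized assistance with reference conditions
#'
#' Simulates equal-duration walking bouts under four conditions — no device,
#' zero-torque (transparent) mode, fixed maximum torque (20, -20) Nm, and the
#' optimized HITL profile — and reports the median estimated metabolic cost
#' and median interaction torque per condition, plus percent changes relative
#' to the zero-torque and no-device baselines
#' (`100 * (baseline - condition) / baseline`; positive = reduction).
#'
#' @param user a [synthetic_user()].
#' @param model the fitted [egpr] estimator.
#' @param optimal_peaks length-2 vector (flexion, extension) from
#'   [run_hitl()].
#' @param n_windows 10-s windows simulated per condition (default 12, i.e.
#'   2 min per condition).
#' @param it_method see [collapse_interaction_torque()].
#' @param seed RNG seed for the private stream.
#' @return Object of class `condition_report`: `$conditions` (data frame with
#'   mc_median, it_median), `$percent_vs_zero_torque`,
#'   `$percent_vs_no_device`.
#' @export
compare_conditions <- function(user, model, optimal_peaks, n_windows = 12,
                               it_method = "mean_abs", seed = 1L) {
  stopifnot(inherits(user, "synthetic_user"), inherits(model, "egpr"),
            length(optimal_peaks) == 2, n_windows >= 1)
  with_seed(seed, {
    level_spec <- list(
      no_device = list(mc = user$mc_no_device, it = 0),
      zero_torque = list(mc = user$mc_zero_torque, it = user$it_zero_torque),
      fixed_torque = list(mc = true_mc(user, 20, -20),
                          it = true_it(user, 20, -20)),
      hitl_optimal = list(mc = true_mc(user, optimal_peaks[1],
                                       optimal_peaks[2]),
                          it = true_it(user, optimal_peaks[1],
                                       optimal_peaks[2])))
    rows <- lapply(names(level_spec), function(cond) {
      lv <- level_spec[[cond]]
      mc_est <- it_col <- numeric(n_windows)
      for (k in seq_len(n_windows)) {
        bout <- bout_from_levels(user, lv$mc, lv$it)
        feats <- preprocess_stream(bout$accel, user$bmi)
        mc_est[k] <- predict(model, feats[1, ])
        it_col[k] <- collapse_interaction_torque(bout$it_series, it_method,
                                                 rate = bout$accel$rate)
      }
      data.frame(condition = cond, mc_median = stats::median(mc_est),
                 it_median = stats::median(it_col))
    })
    conditions <- do.call(rbind, rows)
    rownames(conditions) <- conditions$condition
    pct <- function(baseline, col) {
      base <- conditions[baseline, col]
      stats::setNames(100 * (base - conditions[[col]]) / base,
                      conditions$condition)
    }
    structure(list(conditions = conditions,
                   percent_vs_zero_torque = list(
                     mc = pct("zero_torque", "mc_median"),
                     it = pct("zero_torque", "it_median")),
                   percent_vs_no_device = list(
                     mc = pct("no_device", "mc_median")),
                   optimal_peaks = optimal_peaks, n_windows = n_windows),
              class = "condition_report")
  })
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("Condition comparison (%d x 10-s windows per condition)\n",
              x$n_windows))
  cat(sprintf("  optimal peaks: (%.2f, %.2f) Nm\n",
              x$optimal_peaks[1], x$optimal_peaks[2]))
  print(x$conditions[, c("mc_median", "it_median")], digits = 4)
  cat(sprintf("  HITL vs zero-torque: mc %+.1f%%, it %+.1f%%\n",
              x$percent_vs_zero_torque$mc[["hitl_optimal"]],
              x$percent_vs_zero_torque$it[["hitl_optimal"]]))
  cat(sprintf("  HITL vs no-device:   mc %+.1f%%\n",
              x$percent_vs_no_device$mc[["hitl_optimal"]]))
  invisible(x)
}

#' Load a simulation configuration from a YAML file
#'
#' The file may hold three top-level sections — `user`, `cmaes`, `cost` —
#' whose keys are passed to [synthetic_user()], [cmaes_config()] and the
#' cost-function arguments of [run_hitl()] respectively; omitted keys keep
#' the package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `user` (a `synthetic_user`), `cmaes` (a
#'   `cmaes_config`) and `cost` (list with `w1`, `w2`, `it_method`).
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cost <- list(w1 = 1, w2 = 1, it_method = "mean_abs")
  cost[names(cfg$cost)] <- cfg$cost
  list(user = do.call(synthetic_user, as.list(cfg$user)),
       cmaes = do.call(cmaes_config, as.list(cfg$cmaes)),
       cost = cost)
}

#' Write a condition report as JSON
#'
#' @param report a `condition_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  obj <- list(conditions = report$conditions,
              percent_vs_zero_torque = report$percent_vs_zero_torque,
              percent_vs_no_device = report$percent_vs_no_device,
              optimal_peaks = report$optimal_peaks)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
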