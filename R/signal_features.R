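#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim rnorm runif sd var median qnorm cor
#' @importFrom utils read.csv write.csv head tail
NULL

# Fixed channel ordering used everywhere: four body sites, each x -> y -> z.
ACCEL_SITES <- c("chest", "wrist", "waist", "ankle")
ACCEL_CHANNELS <- as.vector(t(outer(ACCEL_SITES, c("x", "y", "z"), paste, sep = "_")))

#' Multi-site accelerometer stream
#'
#' Container for synchronized 3-axis acceleration from the four body sites used
#' by the metabolic-cost estimator (chest, right wrist, left waist, right
#' ankle), uniformly sampled at a common rate.
#'
#' @param data numeric matrix, samples x 12 channels, in m/s^2. Columns must be
#'   (or are assumed to be) in the fixed order chest/wrist/waist/ankle, each
#'   x, y, z.
#' @param rate sampling rate in Hz (default 100).
#' @return An object of class `accel_stream`.
#' @export
accel_stream <- function(data, rate = 100) {
  data <- as.matrix(data)
  if (ncol(data) != 12L)
    stop("accel_stream needs exactly 12 channels (4 sites x 3 axes), got ",
         ncol(data))
  if (anyNA(data)) stop("accel_stream must not contain missing values")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  colnames(data) <- ACCEL_CHANNELS
  structure(list(data = data, rate = rate, sites = ACCEL_SITES),
            class = "accel_stream")
}

#' @export
print.accel_stream <- function(x, ...) {
  cat(sprintf("<accel_stream> %d samples x 12 channels @ %g Hz (%.2f s)\n",
              nrow(x$data), x$rate, nrow(x$data) / x$rate))
  invisible(x)
}

# Butterworth coefficient cache: design is delegated to signal::butter, the
# (cheap) application runs through stats::filter below.
.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(order, cutoff_hz, rate) {
  key <- paste(order, cutoff_hz, rate, sep = "|")
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
    .butter_cache[[key]] <- bf
  }
  bf
}

# One causal IIR pass, initialized at steady state for the buffer's first
# sample (no onset transient on block-wise buffers): by linearity,
# y = L(x - x[1]) + dc_gain * x[1] where L is the zero-state filter.
iir_pass <- function(b, a, x) {
  x1 <- x[1L]
  xc <- x - x1
  v <- stats::filter(c(rep(0, length(b) - 1L), xc), b,
                     method = "convolution", sides = 1L)
  v <- v[-seq_len(length(b) - 1L)]
  y <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  y + x1 * (sum(b) / sum(a))
}

#' Low-pass filter an acceleration stream
#'
#' Butterworth low-pass filter applied independently to each of the 12
#' channels. The default is zero-phase (forward-backward) filtering, which is
#' appropriate for block-wise processing of 10-s windows and avoids group
#' delay at the cost of doubling the effective order; set `zero_phase = FALSE`
#' for a single causal pass with the nominal magnitude response (gain
#' \eqn{1/\sqrt{2}} at the cutoff for any order).
#'
#' @param stream an [accel_stream].
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency in Hz (default 20); must be below the
#'   Nyquist frequency.
#' @param zero_phase logical; forward-backward filtering (default `TRUE`).
#' @return A filtered [accel_stream] of identical shape.
#' @export
lowpass_filter <- function(stream, order = 4, cutoff_hz = 20,
                           zero_phase = TRUE) {
  stopifnot(inherits(stream, "accel_stream"))
  if (order < 1) stop("filter order must be >= 1")
  if (cutoff_hz >= stream$rate / 2)
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency (",
         stream$rate / 2, " Hz)")
  bf <- butter_coefs(order, cutoff_hz, stream$rate)
  out <- stream$data
  for (j in seq_len(ncol(out))) {
    y <- iir_pass(bf$b, bf$a, out[, j])
    if (zero_phase) y <- rev(iir_pass(bf$b, bf$a, rev(y)))
    out[, j] <- y
  }
  accel_stream(out, stream$rate)
}

#' Split a stream into non-overlapping windows
#'
#' Tumbling (non-overlapping, contiguous) windows; a trailing partial window is
#' discarded.
#'
#' @param stream an [accel_stream].
#' @param window_seconds window duration in seconds (default 10).
#' @return A list of `accel_window` objects, each holding exactly
#'   `window_seconds * rate` samples per channel.
#' @export
window_stream <- function(stream, window_seconds = 10) {
  stopifnot(inherits(stream, "accel_stream"))
  len <- round(window_seconds * stream$rate)
  n <- nrow(stream$data)
  if (n < len)
    stop("stream (", n, " samples) is shorter than one window (", len,
         " samples)")
  k <- n %/% len
  lapply(seq_len(k), function(i) {
    structure(list(data = stream$data[((i - 1L) * len + 1L):(i * len), ,
                                      drop = FALSE],
                   rate = stream$rate, window_seconds = window_seconds),
              class = "accel_window")
  })
}

#' Mean absolute deviation about the mean
#'
#' The per-channel feature of the estimator: mean of absolute deviations from
#' the arithmetic mean. (Distinct from [stats::mad()], which is median-based.)
#'
#' @param x numeric vector, length >= 1.
#' @return Non-negative scalar.
#' @export
mean_abs_dev <- function(x) {
  if (length(x) == 0L) stop("mean_abs_dev: empty input")
  mean(abs(x - mean(x)))
}

#' Extract the 13-entry feature vector from one window
#'
#' Computes the MAD of each of the 12 acceleration channels (fixed order:
#' chest, wrist, waist, ankle, each x, y, z) and appends the subject's BMI.
#'
#' @param window an `accel_window` from [window_stream()].
#' @param bmi body mass index in kg/m^2 (> 0).
#' @return Named numeric vector of length 13 with attribute
#'   `normalized = FALSE`.
#' @export
extract_features <- function(window, bmi) {
  stopifnot(inherits(window, "accel_window"))
  if (!is.numeric(bmi) || length(bmi) != 1L || bmi <= 0)
    stop("bmi must be a single positive number")
  f <- c(apply(window$data, 2L, mean_abs_dev), bmi)
  names(f) <- c(paste0("mad_", ACCEL_CHANNELS), "bmi")
  attr(f, "normalized") <- FALSE
  f
}

#' Fit a z-score normalizer
#'
#' Learns per-feature mean and (population) standard deviation on a training
#' set of feature vectors. Population SD is used so apply/invert round-trips
#' are exact on the fitting set.
#'
#' @param features matrix (rows = observations) or list of feature vectors.
#' @return Object of class `feature_normalizer` with `$mean` and `$sd`.
#' @export
fit_normalizer <- function(features) {
  x <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  if (nrow(x) < 2L) stop("fit_normalizer needs at least 2 feature vectors")
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, m)^2))  # population SD
  if (any(s <= 0)) {
    bad <- which(s <= 0)
    stop("degenerate (zero-variance) feature at index ",
         paste(bad, collapse = ", "))
  }
  structure(list(mean = m, sd = s, sd_type = "population"),
            class = "feature_normalizer")
}

#' Apply a fitted z-score normalizer
#'
#' @param feature feature vector (or matrix of rows) from [extract_features()].
#' @param stats a `feature_normalizer`.
#' @return Normalized feature(s) with attribute `normalized = TRUE`.
#' @export
apply_normalizer <- function(feature, stats) {
  stopifnot(inherits(stats, "feature_normalizer"))
  if (isTRUE(attr(feature, "normalized")))
    stop("feature is already normalized")
  if (is.matrix(feature)) {
    if (ncol(feature) != length(stats$mean))
      stop("feature dimension (", ncol(feature),
           ") does not match normalizer (", length(stats$mean), ")")
    z <- sweep(sweep(feature, 2L, stats$mean), 2L, stats$sd, "/")
  } else {
    if (length(feature) != length(stats$mean))
      stop("feature dimension (", length(feature),
           ") does not match normalizer (", length(stats$mean), ")")
    z <- (feature - stats$mean) / stats$sd
  }
  attr(z, "normalized") <- TRUE
  z
}

#' Invert a z-score normalization
#'
#' @param z normalized feature vector or matrix.
#' @param stats the `feature_normalizer` used to normalize.
#' @return Features on the original scale.
#' @export
invert_normalizer <- function(z, stats) {
  stopifnot(inherits(stats, "feature_normalizer"))
  x <- if (is.matrix(z)) sweep(sweep(z, 2L, stats$sd, "*"), 2L, stats$mean, "+")
       else z * stats$sd + stats$mean
  attr(x, "normalized") <- FALSE
  x
}

#' Read / write an accelerometer recording as CSV
#'
#' Columns: `time_s`, then the 12 channels `<site>_<axis>` in the fixed order
#' chest, wrist, waist, ankle, each x, y, z. Header row mandatory.
#'
#' @param path file path.
#' @param stream an [accel_stream] (for writing).
#' @return [accel_stream] (reading) or `path`, invisibly (writing).
#' @export
read_accel_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("time_s", ACCEL_CHANNELS), names(d))
  if (length(missing))
    stop("accelerometer CSV is missing columns: ",
         paste(missing, collapse = ", "))
  dt <- diff(d$time_s)
  rate <- 1 / stats::median(dt)
  accel_stream(as.matrix(d[, ACCEL_CHANNELS]), rate = rate)
}

#' @rdname read_accel_csv
#' @export
write_accel_csv <- function(stream, path) {
  stopifnot(inherits(stream, "accel_stream"))
  d <- data.frame(time_s = (seq_len(nrow(stream$data)) - 1L) / stream$rate,
                  stream$data, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Full estimator preprocessing pipeline for one recording
#'
#' Filter -> window -> per-window MAD features with BMI appended; the pipeline
#' behind real-time metabolic-cost estimation.
#'
#' @param stream an [accel_stream].
#' @param bmi subject BMI (kg/m^2).
#' @param order,cutoff_hz,zero_phase see [lowpass_filter()].
#' @param window_seconds see [window_stream()].
#' @return Matrix of raw (unnormalized) feature vectors, one row per window.
#' @export
preprocess_stream <- function(stream, bmi, order = 4, cutoff_hz = 20,
                              zero_phase = TRUE, window_seconds = 10) {
  filtered <- lowpass_filter(stream, order, cutoff_hz, zero_phase)
  wins <- window_stream(filtered, window_seconds)
  do.call(rbind, lapply(wins, extract_features, bmi = bmi))
}
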