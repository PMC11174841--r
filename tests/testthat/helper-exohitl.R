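# Shared fixture builders. Everything is generated in code; heavier fixtures
# (trained estimators) are memoized per test run.

.fixtures <- new.env(parent = emptyenv())

# Sinusoid-filled stream: one frequency per channel or a single frequency.
sine_stream <- function(freq = 3, rate = 100, seconds = 10, amp = 1) {
  n <- round(seconds * rate)
  tt <- (seq_len(n) - 1) / rate
  freqs <- rep_len(freq, 12)
  accel_stream(sapply(freqs, function(f) amp * sin(2 * pi * f * tt)),
               rate = rate)
}

# Amplitude of the component at frequency f, via projection on sin/cos over
# [i0+1, i0+n] (integer number of cycles recommended).
component_amplitude <- function(y, f, rate, i0, n) {
  tt <- (i0:(i0 + n - 1)) / rate
  yy <- y[(i0 + 1):(i0 + n)]
  2 * sqrt(mean(yy * sin(2 * pi * f * tt))^2 +
             mean(yy * cos(2 * pi * f * tt))^2)
}

# Noise-free synthetic user (cost minimum at 18.0 / -17.9 Nm).
noisefree_user <- function(...) {
  synthetic_user(noise_sd_mc = 0, noise_sd_it = 0, noise_sd_accel = 0, ...)
}

# Memoized trained estimators so several test files can share them.
get_model <- function(key = c("noisefree", "default")) {
  key <- match.arg(key)
  if (is.null(.fixtures[[key]])) {
    user <- if (key == "noisefree") noisefree_user() else synthetic_user()
    .fixtures[[key]] <- train_estimator(user, seed = 11)
    .fixtures[[paste0(key, "_user")]] <- user
  }
  .fixtures[[key]]
}

get_user <- function(key = c("noisefree", "default")) {
  key <- match.arg(key)
  get_model(key)
  .fixtures[[paste0(key, "_user")]]
}

# Random raw feature matrix (13 columns, positive MAD-like values + BMI).
random_features <- function(n, seed = 1) {
  withr::with_seed(seed, {
    cbind(matrix(abs(rnorm(n * 12, 1, 0.4)), n, 12),
          runif(n, 22, 30))
  })
}
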