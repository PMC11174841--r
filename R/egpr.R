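# Exponential-kernel Gaussian process regression (EGPR): the metabolic-cost
# estimator. Targets are centered by their training mean; the kernel is
# isotropic over the 13 z-scored features (12 MADs + BMI).

#' Exponential covariance kernel
#'
#' \eqn{k(x,z) = \sigma_f^2 \exp(-\lVert x - z\rVert / \ell)} with length
#' scale \eqn{\ell =} `kernel_scale` and amplitude \eqn{\sigma_f^2 =}
#' `signal_variance`. Symmetric; `k(x,x) = signal_variance`.
#'
#' @param x,z numeric feature vectors of equal length.
#' @param kernel_scale length scale (> 0).
#' @param signal_variance kernel amplitude (default 1).
#' @return Scalar covariance.
#' @export
exponential_kernel <- function(x, z, kernel_scale, signal_variance = 1) {
  if (length(x) != length(z))
    stop("exponential_kernel: dimension mismatch (", length(x), " vs ",
         length(z), ")")
  stopifnot(kernel_scale > 0)
  signal_variance * exp(-sqrt(sum((x - z)^2)) / kernel_scale)
}

# Kernel matrix between rows of X and rows of Z (both already normalized).
exp_kernel_matrix <- function(X, Z, kernel_scale, signal_variance) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  signal_variance * exp(-sqrt(d2) / kernel_scale)
}

# Cholesky with jitter escalation (1e-10 * 10^k up to 1e-6).
chol_with_jitter <- function(A, jitter0 = 1e-10, jitter_max = 1e-6) {
  jit <- jitter0
  repeat {
    R <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jit))
    if (jit >= jitter_max)
      stop("kernel system not positive definite after jitter escalation to ",
           jitter_max)
    jit <- jit * 10
  }
}

# Negative log marginal likelihood of the centered-target GP.
egpr_nll <- function(log_theta, free, fixed, X, yc, jitter0) {
  th <- fixed
  th[free] <- exp(log_theta)
  K <- exp_kernel_matrix(X, X, th[["kernel_scale"]], th[["signal_variance"]])
  ch <- tryCatch(
    chol_with_jitter(K + diag(th[["noise_variance"]], nrow(X)), jitter0),
    error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch$R, forwardsolve(t(ch$R), yc))
  val <- 0.5 * sum(yc * a) + sum(log(diag(ch$R))) +
    0.5 * length(yc) * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit an exponential-kernel Gaussian process regressor
#'
#' Fits the metabolic-cost estimator: a GP with exponential covariance over
#' z-scored features. Features are normalized internally (the normalizer is
#' stored with the model), targets are centered by their training mean, and
#' any hyperparameter not supplied explicitly is fit by maximizing the log
#' marginal likelihood.
#'
#' The single published tuning constant `sigma = 0.15` can play two roles:
#' with `sigma_role = "noise_sd"` (default) it initializes the observation
#' noise standard deviation before marginal-likelihood refinement, following
#' the convention in which "Sigma" names the GP noise SD; with
#' `sigma_role = "length_scale"` it is taken as the kernel length scale on
#' z-scored features and held fixed while the variances are fit.
#'
#' @param x numeric matrix of raw feature vectors (rows = observations,
#'   typically 13 columns: 12 MADs + BMI), or pre-normalized features (set
#'   `normalizer` to the stats used).
#' @param y numeric vector of metabolic-cost targets in W/kg.
#' @param kernel_scale,signal_variance,noise_variance optional fixed
#'   hyperparameters; any left `NULL` is fit by marginal likelihood (except as
#'   implied by `sigma_role`). `noise_variance = 0` requests an interpolating
#'   (noise-free) fit.
#' @param sigma the published tuning constant (default 0.15); see
#'   `sigma_role`.
#' @param sigma_role `"noise_sd"` (default) or `"length_scale"`.
#' @param jitter initial diagonal stabilizer (default 1e-10, escalated x10 up
#'   to 1e-6 before erroring).
#' @param normalizer optional `feature_normalizer`; if omitted one is fit on
#'   `x`.
#' @return Object of class `egpr` with methods [predict.egpr()],
#'   `print`, `summary`, `coef` (hyperparameters), `fitted`, `residuals`.
#' @export
egpr <- function(x, y, kernel_scale = NULL, signal_variance = NULL,
                 noise_variance = NULL, sigma = 0.15,
                 sigma_role = c("noise_sd", "length_scale"),
                 jitter = 1e-10, normalizer = NULL) {
  sigma_role <- match.arg(sigma_role)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (length(y) < 1L) stop("egpr needs at least one training point")

  if (is.null(normalizer)) {
    if (isTRUE(attr(x, "normalized")))
      stop("pre-normalized features require the fitting normalizer")
    normalizer <- if (nrow(x) >= 2L) fit_normalizer(x) else NULL
  }
  Z <- if (is.null(normalizer)) x else
    if (isTRUE(attr(x, "normalized"))) x else apply_normalizer(x, normalizer)
  Z <- unclass(Z); attr(Z, "normalized") <- NULL

  theta <- c(kernel_scale = NA_real_, signal_variance = NA_real_,
             noise_variance = NA_real_)
  if (!is.null(kernel_scale)) theta[["kernel_scale"]] <- kernel_scale
  if (!is.null(signal_variance)) theta[["signal_variance"]] <- signal_variance
  if (!is.null(noise_variance)) theta[["noise_variance"]] <- noise_variance
  if (sigma_role == "length_scale" && is.null(kernel_scale))
    theta[["kernel_scale"]] <- sigma

  # Initial values for free hyperparameters.
  init <- theta
  if (is.na(init[["kernel_scale"]])) {
    d <- stats::dist(Z)
    md <- if (length(d)) stats::median(d[d > 0]) else 1
    init[["kernel_scale"]] <- if (is.finite(md) && md > 0) md else 1
  }
  vy <- if (length(y) > 1L) stats::var(y) else 1
  if (is.na(init[["signal_variance"]]))
    init[["signal_variance"]] <- max(vy, 1e-6)
  if (is.na(init[["noise_variance"]]))
    init[["noise_variance"]] <- if (sigma_role == "noise_sd") sigma^2
                                else max(0.01 * vy, 1e-8)

  free <- names(theta)[is.na(theta)]
  ybar <- mean(y)
  yc <- y - ybar
  fit_info <- NULL
  if (length(free) > 0L && length(y) >= 2L) {
    opt <- stats::optim(log(init[free]), egpr_nll, method = "L-BFGS-B",
                        lower = log(1e-6), upper = log(1e6),
                        free = free, fixed = init, X = Z, yc = yc,
                        jitter0 = jitter)
    theta[free] <- exp(opt$par)
    fit_info <- list(free = free, nll = opt$value,
                     convergence = opt$convergence)
  } else {
    theta[free] <- init[free]
  }

  K <- exp_kernel_matrix(Z, Z, theta[["kernel_scale"]],
                         theta[["signal_variance"]])
  ch <- chol_with_jitter(K + diag(theta[["noise_variance"]], nrow(Z)), jitter)
  alpha <- backsolve(ch$R, forwardsolve(t(ch$R), yc))

  structure(list(X = Z, y = y, ybar = ybar, alpha = alpha,
                 theta = theta, jitter_used = ch$jitter,
                 sigma = sigma, sigma_role = sigma_role,
                 normalizer = normalizer, fit_info = fit_info,
                 chol = ch$R),
            class = "egpr")
}

#' Predict metabolic cost from an EGPR model
#'
#' Posterior mean at new feature vectors. Raw features are normalized with the
#' model's stored stats; features already carrying `normalized = TRUE` are
#' used as-is.
#'
#' @param object an [egpr] model.
#' @param newdata feature vector or matrix of rows.
#' @param ... unused.
#' @return Numeric vector of posterior-mean predictions (W/kg).
#' @export
predict.egpr <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         ncol(object$X))
  Z <- if (isTRUE(attr(newdata, "normalized")) || is.null(object$normalizer))
    newdata else apply_normalizer(newdata, object$normalizer)
  Ks <- exp_kernel_matrix(unclass(Z), object$X, object$theta[["kernel_scale"]],
                          object$theta[["signal_variance"]])
  as.numeric(object$ybar + Ks %*% object$alpha)
}

#' @export
fitted.egpr <- function(object, ...) {
  K <- exp_kernel_matrix(object$X, object$X, object$theta[["kernel_scale"]],
                         object$theta[["signal_variance"]])
  as.numeric(object$ybar + K %*% object$alpha)
}

#' @export
residuals.egpr <- function(object, ...) object$y - fitted(object)

#' @export
coef.egpr <- function(object, ...) object$theta

#' @export
print.egpr <- function(x, ...) {
  cat(sprintf(paste0("<egpr> exponential-kernel GP, %d training points, ",
                     "%d features\n"), nrow(x$X), ncol(x$X)))
  cat(sprintf("  kernel_scale=%.4g  signal_variance=%.4g  noise_variance=%.4g",
              x$theta[["kernel_scale"]], x$theta[["signal_variance"]],
              x$theta[["noise_variance"]]))
  cat(sprintf("  (sigma=%.3g as %s)\n", x$sigma, x$sigma_role))
  invisible(x)
}

#' @export
summary.egpr <- function(object, ...) {
  r <- residuals(object)
  out <- list(model = object, rmse_train = rmse(object$y, object$y - r),
              n = length(object$y))
  class(out) <- "summary.egpr"
  out
}

#' @export
print.summary.egpr <- function(x, ...) {
  print(x$model)
  cat(sprintf("  in-sample RMSE: %.4g W/kg over %d points\n",
              x$rmse_train, x$n))
  if (!is.null(x$model$fit_info))
    cat("  hyperparameters fit by marginal likelihood: ",
        paste(x$model$fit_info$free, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- agreement metrics -----------------------------------------------------

#' Root mean squared error
#' @param y,yhat numeric vectors of equal length.
#' @return \eqn{\sqrt{\frac{1}{N}\sum_i (y_i - \hat y_i)^2}}
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("rmse: length mismatch (", length(y), " vs ", length(yhat), ")")
  if (length(y) < 1L) stop("rmse: empty input")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute percentage error
#'
#' Returned as a fraction (multiply by 100 for percent).
#' @param y ground truth (all non-zero).
#' @param yhat estimates.
#' @export
mape <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("mape: length mismatch (", length(y), " vs ", length(yhat), ")")
  if (any(y == 0)) stop("mape: ground truth contains zeros")
  mean(abs(y - yhat) / abs(y))
}

#' Bland-Altman agreement analysis
#'
#' Bias and 1.96-SD limits of agreement of the differences
#' `y - yhat` (ground truth minus estimate), with per-pair means for plotting.
#'
#' @param y ground-truth values.
#' @param yhat estimates.
#' @return Object of class `bland_altman`: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff`, `n`, plus the per-pair `means` and `diffs`.
#' @export
bland_altman <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("bland_altman: length mismatch")
  if (length(y) < 2L) stop("bland_altman needs at least 2 pairs")
  d <- y - yhat
  s <- stats::sd(d)
  structure(list(bias = mean(d), sd_diff = s,
                 loa_lower = mean(d) - 1.96 * s,
                 loa_upper = mean(d) + 1.96 * s,
                 n = length(d), means = (y + yhat) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n=%d)\n", x$n))
  cat(sprintf("  bias: %.4g   limits of agreement: [%.4g, %.4g]\n",
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (truth - estimate)", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$loa_lower, x$bias, x$loa_upper),
                   lty = c(2, 1, 2), col = c("blue", "black", "red"))
  invisible(x)
}

# Pooled + per-fold agreement summary used by loso_cv.
agreement_report <- function(y, yhat) {
  ba <- bland_altman(y, yhat)
  list(rmse = rmse(y, yhat), mape = mape(y, yhat), bias = ba$bias,
       loa_lower = ba$loa_lower, loa_upper = ba$loa_upper, n = length(y))
}

#' Leave-one-subject-out cross-validation of the estimator
#'
#' For each subject, fits the normalizer and the GP on all other subjects'
#' data and predicts the held-out subject. Reports per-fold and pooled
#' agreement metrics (RMSE, MAPE, Bland-Altman bias and limits).
#'
#' @param features matrix of raw feature vectors (rows = observations).
#' @param targets metabolic-cost targets (W/kg).
#' @param subjects subject identifier per row (>= 2 distinct values).
#' @param ... passed to [egpr()] (hyperparameter settings).
#' @return Object of class `loso_cv`: `$folds` (named list of agreement
#'   reports), `$pooled`, `$predictions` (data frame with subject, y, yhat).
#' @export
loso_cv <- function(features, targets, subjects, ...) {
  features <- as.matrix(features)
  subjects <- as.character(subjects)
  ids <- unique(subjects)
  if (length(ids) < 2L)
    stop("loso_cv needs at least 2 subjects, got ", length(ids))
  preds <- numeric(length(targets))
  folds <- list()
  for (s in sort(ids)) {
    hold <- subjects == s
    fit <- egpr(features[!hold, , drop = FALSE], targets[!hold], ...)
    preds[hold] <- predict(fit, features[hold, , drop = FALSE])
    folds[[s]] <- agreement_report(targets[hold], preds[hold])
  }
  structure(list(folds = folds,
                 pooled = agreement_report(targets, preds),
                 predictions = data.frame(subject = subjects, y = targets,
                                          yhat = preds)),
            class = "loso_cv")
}

#' @export
print.loso_cv <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV over %d subjects (%d estimates)\n",
              length(x$folds), x$pooled$n))
  cat(sprintf("  pooled RMSE %.3f W/kg, MAPE %.1f%%, bias %.3f W/kg\n",
              x$pooled$rmse, 100 * x$pooled$mape, x$pooled$bias))
  for (s in names(x$folds))
    cat(sprintf("  fold %-8s RMSE %.3f  MAPE %.1f%%  n=%d\n", s,
                x$folds[[s]]$rmse, 100 * x$folds[[s]]$mape, x$folds[[s]]$n))
  invisible(x)
}

# ---- persistence -----------------------------------------------------------

#' Save / load an EGPR model as plain text (JSON)
#'
#' The archive stores training inputs and targets, hyperparameters, the
#' feature normalizer, and a format-version field.
#'
#' @param model an [egpr] model.
#' @param path file path.
#' @export
write_egpr <- function(model, path) {
  stopifnot(inherits(model, "egpr"))
  obj <- list(format_version = 1L,
              X = unname(as.matrix(model$X)), y = model$y, ybar = model$ybar,
              theta = as.list(model$theta), sigma = model$sigma,
              sigma_role = model$sigma_role,
              normalizer = if (is.null(model$normalizer)) NULL else
                list(mean = unname(model$normalizer$mean),
                     sd = unname(model$normalizer$sd)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_egpr
#' @export
read_egpr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported egpr archive format")
  norm <- if (is.null(obj$normalizer)) NULL else
    structure(list(mean = obj$normalizer$mean, sd = obj$normalizer$sd,
                   sd_type = "population"), class = "feature_normalizer")
  X <- as.matrix(obj$X); attr(X, "normalized") <- TRUE
  egpr(X, obj$y,
       kernel_scale = obj$theta$kernel_scale,
       signal_variance = obj$theta$signal_variance,
       noise_variance = obj$theta$noise_variance,
       sigma = obj$sigma, sigma_role = obj$sigma_role,
       normalizer = norm)
}
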