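#' Squared exponential covariance function
#'
#' Evaluates \eqn{k(t_i, t_j) = \sigma_f^2 \exp(-(t_i - t_j)^2 / (2 l^2))}
#' between two sets of time points. The kernel itself is noise-free; the
#' observation-noise term \eqn{\sigma_n^2 \delta_{ij}} belongs to the training
#' covariance and is added exactly once (either here via `include_noise` when
#' both arguments are the same training grid, or by [fit_gpr()]).
#'
#' @param t_a,t_b Numeric vectors of times (days).
#' @param theta A [hyperparams()] object.
#' @param include_noise If `TRUE` and `t_a`/`t_b` are the identical grid, add
#'   `sigma_n^2` on the diagonal.
#' @return A `length(t_a) x length(t_b)` covariance matrix; symmetric positive
#'   semi-definite when `t_a == t_b`.
#' @examples
#' th <- hyperparams(0, 0, -10) # l = 1 day, sigma_f = 1, near-zero noise
#' se_kernel(0, 1, th) # exp(-0.5)
#' @export
se_kernel <- function(t_a, t_b, theta, include_noise = FALSE) {
  stopifnot(inherits(theta, "gpr_theta"))
  t_a <- as.numeric(t_a); t_b <- as.numeric(t_b)
  if (!all(is.finite(t_a)) || !all(is.finite(t_b)))
    stop(errorCondition("non-finite time inputs to se_kernel",
                        class = c("phenofill_invalid_input", "error", "condition")))
  lin <- theta_linear(theta)
  d <- outer(t_a, t_b, "-")
  K <- lin[["sigma_f2"]] * exp(-(d * d) / (2 * lin[["l"]]^2))
  if (include_noise && length(t_a) == length(t_b) && all(t_a == t_b))
    K <- K + diag(lin[["sigma_n2"]], length(t_a))
  K
}

# Cholesky of C = K + sigma_n^2 I with escalating jitter.
# Returns list(R = upper factor, jitter).
chol_with_jitter <- function(C) {
  n <- nrow(C)
  base <- sum(diag(C)) / n
  jit <- 0
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * base
    while (jit <= 1e-4 * base) {
      R <- tryCatch(chol(C + diag(jit, n)), error = function(e) NULL)
      if (!is.null(R)) break
      jit <- jit * 10
    }
  }
  if (is.null(R))
    stop(errorCondition("covariance factorization failed after maximum jitter",
                        class = c("phenofill_numerical", "error", "condition")))
  list(R = R, jitter = jit)
}

#' Condition a GP on one pixel's observations
#'
#' Builds and factorises the training covariance `C = K + sigma_n^2 I`
#' (Cholesky, with escalating jitter on failure) and solves for the weight
#' vector `alpha = C^-1 y`. The factorisation is shared by the predictive
#' distribution, the log marginal likelihood and its gradient.
#'
#' @param ts A [time_series()].
#' @param theta A [hyperparams()].
#' @param min_obs Minimum number of valid observations required (default 4);
#'   pixels below it raise an insufficient-data error and are flagged, not
#'   fitted, by the stack-level drivers.
#' @return An object of class `gpr_fit` with fields `theta`, `train_times`,
#'   `train_values`, `alpha`, `chol_upper`, `jitter_used`.
#' @export
fit_gpr <- function(ts, theta, min_obs = 4L) {
  stopifnot(inherits(ts, "pixel_ts"), inherits(theta, "gpr_theta"))
  t <- valid_times(ts); y <- valid_values(ts)
  if (length(t) < min_obs)
    stop(errorCondition(
      sprintf("need >= %d valid observations, got %d", min_obs, length(t)),
      class = c("phenofill_insufficient_data", "error", "condition")))
  lin <- theta_linear(theta)
  C <- se_kernel(t, t, theta) + diag(lin[["sigma_n2"]], length(t))
  f <- chol_with_jitter(C)
  alpha <- backsolve(f$R, backsolve(f$R, y, transpose = TRUE))
  structure(list(theta = theta, train_times = t, train_values = y,
                 alpha = as.numeric(alpha), chol_upper = f$R,
                 jitter_used = f$jitter, epoch = ts$epoch),
            class = "gpr_fit")
}

#' @export
print.gpr_fit <- function(x, ...) {
  cat(sprintf("<gpr_fit> n=%d, l=%.1f d, jitter=%g\n",
              length(x$train_times), theta_linear(x$theta)[["l"]], x$jitter_used))
  invisible(x)
}

#' Log marginal likelihood of a GP fit
#'
#' \deqn{\log p(y | t, \theta) = -\tfrac12 y^\top C^{-1} y
#'   - \tfrac12 \log |C| - \tfrac{n}{2} \log 2\pi, \quad C = K + \sigma_n^2 I}
#' computed through the stored Cholesky factor (no explicit inverse or
#' determinant). The first term measures data fit, the second penalises model
#' complexity.
#'
#' @param ts A [time_series()] (or an existing `gpr_fit`).
#' @param theta A [hyperparams()]; ignored when `ts` is already a fit.
#' @return The log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(ts, theta = NULL) {
  fit <- if (inherits(ts, "gpr_fit")) ts else fit_gpr(ts, theta, min_obs = 1L)
  y <- fit$train_values
  n <- length(y)
  -0.5 * sum(y * fit$alpha) - sum(log(diag(fit$chol_upper))) - n / 2 * log(2 * pi)
}

#' Gradient of the log marginal likelihood
#'
#' Analytic gradient with respect to the log-scale triple
#' `(log(1/l), log sigma_f, log sigma_n)`, via the trace identity
#' \deqn{\partial_j \log p = \tfrac12 \mathrm{tr}\big((\alpha\alpha^\top -
#'   C^{-1})\, \partial C / \partial \theta_j\big)}
#' with the chain rule into the log parameterisation.
#'
#' @inheritParams log_marginal_likelihood
#' @return Numeric length-3 gradient, named as the log triple.
#' @export
lml_gradient <- function(ts, theta = NULL) {
  fit <- if (inherits(ts, "gpr_fit")) ts else fit_gpr(ts, theta, min_obs = 1L)
  th <- fit$theta
  lin <- theta_linear(th)
  t <- fit$train_times
  d2 <- outer(t, t, "-")^2
  K <- lin[["sigma_f2"]] * exp(-d2 / (2 * lin[["l"]]^2))
  Cinv <- chol2inv(fit$chol_upper)
  A <- tcrossprod(fit$alpha) - Cinv
  c(log_inv_l = 0.5 * sum(A * (-K * d2 / lin[["l"]]^2)),
    log_sigma_f = sum(A * K),
    log_sigma_n = lin[["sigma_n2"]] * sum(diag(A)))
}

#' Predictive distribution on new time points
#'
#' \deqn{\mu(t_*) = k_*^\top C^{-1} y, \qquad
#'   \sigma^2(t_*) = c_* - k_*^\top C^{-1} k_*, \qquad
#'   c_* = k(t_*, t_*) + \sigma_n^2.}
#' The predictive variance includes the noise term (it is the variance of a
#' new noisy observation, matching how reconstruction uncertainty is usually
#' mapped). Negative variances from rounding are clipped at zero and the
#' clip magnitude recorded in attribute `"var_clip"`.
#'
#' @param object A `gpr_fit`.
#' @param t_star Numeric vector of prediction times (days since epoch).
#' @param ... Unused.
#' @return An object of class `gpr_prediction`: list with `times`, `mean`,
#'   `sd`.
#' @export
predict.gpr_fit <- function(object, t_star, ...) {
  t_star <- as.numeric(t_star)
  if (!all(is.finite(t_star)))
    stop(errorCondition("non-finite prediction times",
                        class = c("phenofill_invalid_input", "error", "condition")))
  lin <- theta_linear(object$theta)
  Ks <- se_kernel(t_star, object$train_times, object$theta)
  mu <- as.numeric(Ks %*% object$alpha)
  w <- backsolve(object$chol_upper, t(Ks), transpose = TRUE)
  v <- lin[["sigma_f2"]] + lin[["sigma_n2"]] - colSums(w * w)
  clip <- max(0, -min(v, 0))
  v[v < 0] <- 0
  structure(list(times = t_star, mean = mu, sd = sqrt(v), epoch = object$epoch),
            class = "gpr_prediction", var_clip = clip)
}

#' @export
print.gpr_prediction <- function(x, ...) {
  cat(sprintf("<gpr_prediction> %d points, mean in [%.3g, %.3g]\n",
              length(x$times), min(x$mean), max(x$mean)))
  invisible(x)
}
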