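#' Squared-exponential kernel hyperparameters
#'
#' Container for the GPR hyperparameter triple \eqn{\theta = \{l, \sigma_f^2,
#' \sigma_n^2\}} stored on the log scale conventionally used when reporting
#' them: `log(1/l)` (l in days), `log(sigma_f)` and `log(sigma_n)`. The log
#' parameterisation enforces positivity during optimisation and is the scale
#' on which hyperparameter sets are averaged.
#'
#' @param log_inv_l Log of the inverse length-scale, `log(1/l)`, `l` in days.
#' @param log_sigma_f Log of the signal standard deviation.
#' @param log_sigma_n Log of the noise standard deviation.
#' @return An object of class `gpr_theta`.
#' @examples
#' th <- hyperparams(log_inv_l = -3.64, log_sigma_f = -0.48, log_sigma_n = -1.74)
#' theta_linear(th) # length-scale ~ 38 days
#' @export
hyperparams <- function(log_inv_l, log_sigma_f, log_sigma_n) {
  v <- c(log_inv_l = as.numeric(log_inv_l),
         log_sigma_f = as.numeric(log_sigma_f),
         log_sigma_n = as.numeric(log_sigma_n))
  if (length(v) != 3L || !all(is.finite(v)))
    stop("hyperparameters must be three finite numbers", call. = FALSE)
  structure(as.list(v), class = "gpr_theta")
}

#' @export
print.gpr_theta <- function(x, ...) {
  lin <- theta_linear(x)
  cat(sprintf(
    "<gpr_theta>  log(1/l)=%.4f  log(sf)=%.4f  log(sn)=%.4f  (l=%.1f d, sf2=%.4g, sn2=%.4g)\n",
    x$log_inv_l, x$log_sigma_f, x$log_sigma_n,
    lin[["l"]], lin[["sigma_f2"]], lin[["sigma_n2"]]))
  invisible(x)
}

#' @rdname hyperparams
#' @param x A `gpr_theta` object (or log-triple numeric vector for
#'   `theta_from_vector`).
#' @return `theta_linear` returns the linear-scale named vector
#'   `c(l, sigma_f2, sigma_n2)`; the round trip through the log scale is exact
#'   to machine precision.
#' @export
theta_linear <- function(x) {
  stopifnot(inherits(x, "gpr_theta"))
  c(l = exp(-x$log_inv_l),
    sigma_f2 = exp(2 * x$log_sigma_f),
    sigma_n2 = exp(2 * x$log_sigma_n))
}

#' @rdname hyperparams
#' @export
theta_vector <- function(x) {
  stopifnot(inherits(x, "gpr_theta"))
  c(log_inv_l = x$log_inv_l, log_sigma_f = x$log_sigma_f,
    log_sigma_n = x$log_sigma_n)
}

#' @rdname hyperparams
#' @export
theta_from_vector <- function(x) {
  hyperparams(x[[1L]], x[[2L]], x[[3L]])
}

#' Read and write hyperparameters as JSON
#'
#' The JSON layout is `{"log_inv_l": ..., "log_sigma_f": ..., "log_sigma_n":
#' ..., "epoch": "YYYY-MM-DD"}`; the epoch records the day-counting origin the
#' length-scale refers to.
#'
#' @param theta A `gpr_theta`.
#' @param path File path.
#' @param epoch Epoch date (`Date` or ISO-8601 string) stored alongside.
#' @return `read_theta_json` returns a `gpr_theta` with attribute `"epoch"`.
#' @export
write_theta_json <- function(theta, path, epoch = "2016-01-01") {
  stopifnot(inherits(theta, "gpr_theta"))
  jsonlite::write_json(
    list(log_inv_l = theta$log_inv_l, log_sigma_f = theta$log_sigma_f,
         log_sigma_n = theta$log_sigma_n, epoch = as.character(as.Date(epoch))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_theta_json
#' @export
read_theta_json <- function(path) {
  j <- jsonlite::read_json(path)
  th <- hyperparams(j$log_inv_l, j$log_sigma_f, j$log_sigma_n)
  if (!is.null(j$epoch)) attr(th, "epoch") <- as.Date(j$epoch)
  th
}

#' Published crop hyperparameter presets
#'
#' A ready-made [theta_set()] of squared-exponential GPR hyperparameters
#' estimated over Sentinel-2 LAI time series of nine common crops in a Spanish
#' dryland agricultural region (plus their pixel-weighted global average).
#' They are usable as fixed-kernel defaults when no training data are at hand,
#' in the spirit of toolboxes that ship precalculated kernels for crop
#' monitoring.
#'
#' @return A `theta_set` with per-crop and global entries (log scale, days).
#' @examples
#' ps <- theta_presets()
#' ps$per_crop$wheat
#' ps$global
#' @export
theta_presets <- function() {
  path <- system.file("extdata", "theta_presets.json", package = "phenofill",
                      mustWork = TRUE)
  read_theta_set(path)
}
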