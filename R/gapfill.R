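#' Reconstruct one pixel's continuous series
#'
#' Fits a GP with the given hyperparameters to the pixel's valid observations
#' and predicts mean and uncertainty on the output grid. Pixels with fewer
#' than `min_obs` valid points are not fitted; a flagged all-`NA` prediction
#' is returned instead.
#'
#' @param ts A [time_series()].
#' @param theta A [hyperparams()].
#' @param grid Numeric prediction times (days since the series epoch).
#' @param min_obs Minimum valid observations (default 4).
#' @return A `gpr_prediction` with an extra `flag` field (`"ok"` or
#'   `"insufficient_data"`).
#' @export
reconstruct_pixel <- function(ts, theta, grid, min_obs = 4L) {
  fit <- tryCatch(fit_gpr(ts, theta, min_obs = min_obs),
                  error = function(e) {
                    if (inherits(e, "phenofill_insufficient_data")) NULL
                    else stop(e)
                  })
  if (is.null(fit)) {
    return(structure(list(times = as.numeric(grid),
                          mean = rep(NA_real_, length(grid)),
                          sd = rep(NA_real_, length(grid)),
                          epoch = ts$epoch, flag = "insufficient_data"),
                     class = "gpr_prediction"))
  }
  p <- predict(fit, grid)
  p$flag <- "ok"
  p
}

#' Default regular prediction grid
#'
#' Regular grid over the stack's observed span at a fixed time step
#' (10 days by default, a common reconstruction step for decametric
#' vegetation products); alternatively the acquisition dates themselves.
#'
#' @param stack A [raster_stack()].
#' @param step Grid step in days; `NULL` returns the acquisition times.
#' @return Numeric times in days since the stack epoch.
#' @export
prediction_grid <- function(stack, step = 10) {
  tms <- stack_times(stack)
  if (is.null(step)) return(tms)
  seq(min(tms), max(tms), by = step)
}

# theta resolved per pixel -> H x W list-matrix is wasteful; instead return
# a key matrix plus a key -> theta lookup.
resolve_thetas <- function(stack, thetas, mode, map, fallback_global) {
  H <- dim(stack$data)[2]; W <- dim(stack$data)[3]
  flags <- matrix("ok", H, W)
  if (mode == "fixed") {
    th <- if (inherits(thetas, "gpr_theta")) thetas else thetas$global
    stopifnot(inherits(th, "gpr_theta"))
    key <- matrix("fixed", H, W)
    return(list(key = key, lookup = list(fixed = th), flags = flags))
  }
  if (mode == "global") {
    stopifnot(inherits(thetas, "theta_set"), inherits(thetas$global, "gpr_theta"))
    return(list(key = matrix("global", H, W),
                lookup = list(global = thetas$global), flags = flags))
  }
  if (mode == "per_crop") {
    stopifnot(inherits(thetas, "theta_set"))
    if (is.null(map))
      stop(errorCondition("per-crop mode requires a crop_map",
                          class = c("phenofill_config", "error", "condition")))
    key <- matrix(NA_character_, H, W)
    lookup <- thetas$per_crop
    for (r in seq_len(H)) for (c in seq_len(W)) {
      nm <- class_name(map, map$labels[r, c])
      if (!is.null(nm) && !is.na(nm) && nm %in% names(lookup)) {
        key[r, c] <- nm
      } else if (fallback_global && !is.null(thetas$global)) {
        key[r, c] <- ".global"
        flags[r, c] <- "fallback_global"
      } else {
        key[r, c] <- NA_character_
        flags[r, c] <- "no_theta"
      }
    }
    if (fallback_global && !is.null(thetas$global))
      lookup$.global <- thetas$global
    return(list(key = key, lookup = lookup, flags = flags))
  }
  stop("unknown theta mode: ", mode)
}

#' Reconstruct a whole image time series
#'
#' Per-pixel GP reconstruction of the stack on a common output grid, under
#' one of four parameterisations:
#' \describe{
#'   \item{`fixed`}{one [hyperparams()] for every pixel;}
#'   \item{`global`}{the `theta_set`'s global average;}
#'   \item{`per_crop`}{each pixel uses its crop class's average (requires
#'     `crop_map`; unmapped classes fall back to the global average when
#'     `fallback_global` is set, otherwise are flagged);}
#'   \item{`per_pixel`}{hyperparameters trained independently per pixel by
#'     marginal-likelihood maximisation (the conventional, expensive route).}
#' }
#' In the fixed-theta modes no optimiser runs at all, and pixels sharing both
#' a theta and an identical valid-acquisition pattern share one Cholesky
#' factorisation (`share = TRUE`); the shared path is numerically identical
#' to the naive per-pixel loop — it changes cost, never the estimator.
#'
#' @param stack A [raster_stack()].
#' @param thetas A [hyperparams()] (fixed mode), a [theta_set()]
#'   (global/per-crop), or ignored in per-pixel mode.
#' @param mode One of `"fixed"`, `"global"`, `"per_crop"`, `"per_pixel"`.
#' @param crop_map A [crop_map()], required for per-crop mode.
#' @param grid Output times (days since epoch); default regular `step`-day grid.
#' @param step Grid step in days when `grid` is `NULL`.
#' @param share Share factorisations across pixels with identical
#'   (theta, valid-pattern) (default `TRUE`).
#' @param fallback_global In per-crop mode, use the global average for
#'   unmapped classes (default `TRUE`, flagged per pixel).
#' @param pixels Optional data frame (`row`, `col`) restricting computation to
#'   those pixels; others are flagged `"skipped"`.
#' @param min_obs Minimum valid observations per pixel.
#' @param seed Base seed for per-pixel training.
#' @param train_args List of extra arguments for [train_hyperparameters()].
#' @return An object of class `recon_result`: `mean_stack`, `sd_stack`
#'   (`T' x H x W`), `grid` (days), `grid_dates`, `flags` (`H x W` character),
#'   `theta_mode`, `ops` (optimiser-run and factorisation counts), `epoch`,
#'   `geo`, and in per-pixel mode `trained` (the per-pixel theta table).
#' @export
reconstruct_stack <- function(stack, thetas = NULL,
                              mode = c("fixed", "global", "per_crop", "per_pixel"),
                              crop_map = NULL, grid = NULL, step = 10,
                              share = TRUE, fallback_global = TRUE,
                              pixels = NULL, min_obs = 4L, seed = 1L,
                              train_args = list()) {
  stopifnot(inherits(stack, "raster_stack"))
  mode <- match.arg(mode)
  tms <- stack_times(stack)
  if (is.null(grid)) grid <- prediction_grid(stack, step)
  grid <- as.numeric(grid)
  H <- dim(stack$data)[2]; W <- dim(stack$data)[3]
  Tg <- length(grid)
  mean_stack <- array(NA_real_, c(Tg, H, W))
  sd_stack <- array(NA_real_, c(Tg, H, W))
  n_opt <- 0L; n_fact <- 0L
  trained <- NULL

  sel <- matrix(FALSE, H, W)
  if (is.null(pixels)) sel[] <- TRUE
  else sel[cbind(pixels$row, pixels$col)] <- TRUE

  if (mode == "per_pixel") {
    flags <- matrix("skipped", H, W)
    rows <- vector("list", sum(sel))
    i <- 0L
    for (c in seq_len(W)) for (r in seq_len(H)) {
      if (!sel[r, c]) next
      i <- i + 1L
      ts <- pixel_series(stack, r, c)
      tr <- tryCatch(
        do.call(train_hyperparameters,
                c(list(ts = ts, seed = as.integer(seed) + (c - 1L) * H + r,
                       min_obs = min_obs), train_args)),
        error = function(e) NULL)
      if (is.null(tr)) {
        flags[r, c] <- if (n_valid(ts) < min_obs) "insufficient_data" else "failed"
        rows[[i]] <- data.frame(row = r, col = c, log_inv_l = NA_real_,
                                log_sigma_f = NA_real_, log_sigma_n = NA_real_,
                                lml = NA_real_, ok = FALSE)
        next
      }
      n_opt <- n_opt + 1L; n_fact <- n_fact + 1L
      p <- reconstruct_pixel(ts, tr$theta, grid, min_obs = min_obs)
      mean_stack[, r, c] <- p$mean; sd_stack[, r, c] <- p$sd
      flags[r, c] <- p$flag
      rows[[i]] <- data.frame(row = r, col = c,
                              log_inv_l = tr$theta$log_inv_l,
                              log_sigma_f = tr$theta$log_sigma_f,
                              log_sigma_n = tr$theta$log_sigma_n,
                              lml = tr$lml, ok = TRUE)
    }
    trained <- do.call(rbind, rows)
  } else {
    res <- resolve_thetas(stack, thetas, mode, crop_map, fallback_global)
    flags <- res$flags
    flags[!sel] <- "skipped"
    if (!share) {
      for (c in seq_len(W)) for (r in seq_len(H)) {
        if (!sel[r, c] || is.na(res$key[r, c])) next
        p <- reconstruct_pixel(pixel_series(stack, r, c),
                               res$lookup[[res$key[r, c]]], grid,
                               min_obs = min_obs)
        n_fact <- n_fact + (p$flag == "ok")
        mean_stack[, r, c] <- p$mean; sd_stack[, r, c] <- p$sd
        if (p$flag != "ok") flags[r, c] <- p$flag
      }
    } else {
      # group pixels by (theta key, valid-time pattern); one factorization each
      pat <- character(H * W)
      vm <- stack$valid_mask
      fin <- is.finite(stack$data)
      for (c in seq_len(W)) for (r in seq_len(H)) {
        if (!sel[r, c] || is.na(res$key[r, c])) { pat[(c - 1L) * H + r] <- NA; next }
        v <- vm[, r, c] & fin[, r, c]
        pat[(c - 1L) * H + r] <- paste0(res$key[r, c], "|",
                                        paste(as.integer(v), collapse = ""))
      }
      groups <- split(which(!is.na(pat)), pat[!is.na(pat)])
      for (g in groups) {
        r1 <- ((g - 1L) %% H) + 1L; c1 <- ((g - 1L) %/% H) + 1L
        v <- vm[, r1[1], c1[1]] & fin[, r1[1], c1[1]]
        th <- res$lookup[[res$key[r1[1], c1[1]]]]
        if (sum(v) < min_obs) {
          flags[cbind(r1, c1)] <- "insufficient_data"
          next
        }
        tt <- tms[v]
        lin <- theta_linear(th)
        C <- se_kernel(tt, tt, th) + diag(lin[["sigma_n2"]], length(tt))
        fac <- chol_with_jitter(C)
        n_fact <- n_fact + 1L
        Y <- vapply(seq_along(g),
                    function(j) stack$data[v, r1[j], c1[j]],
                    numeric(sum(v)))
        Y <- matrix(Y, nrow = sum(v))
        A <- backsolve(fac$R, backsolve(fac$R, Y, transpose = TRUE))
        Ks <- se_kernel(grid, tt, th)
        M <- Ks %*% A
        wv <- backsolve(fac$R, t(Ks), transpose = TRUE)
        varg <- pmax(lin[["sigma_f2"]] + lin[["sigma_n2"]] - colSums(wv * wv), 0)
        sdg <- sqrt(varg)
        for (j in seq_along(g)) {
          mean_stack[, r1[j], c1[j]] <- M[, j]
          sd_stack[, r1[j], c1[j]] <- sdg
        }
      }
    }
  }

  structure(list(mean_stack = mean_stack, sd_stack = sd_stack,
                 grid = grid, grid_dates = stack$epoch + grid,
                 flags = flags, theta_mode = mode,
                 ops = list(optimizations = n_opt, factorizations = n_fact),
                 epoch = stack$epoch, geo = stack$geo, trained = trained),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  d <- dim(x$mean_stack)
  cat(sprintf("<recon_result> mode=%s, %d grid points x %d x %d px, %d ok pixels\n",
              x$theta_mode, d[1], d[2], d[3], sum(x$flags == "ok")))
  invisible(x)
}

#' @rdname reconstruct_stack
#' @param recon A `recon_result`.
#' @param row,col Pixel indices.
#' @return `recon_series` returns one pixel's reconstruction as a
#'   `gpr_prediction`.
#' @export
recon_series <- function(recon, row, col) {
  structure(list(times = recon$grid, mean = recon$mean_stack[, row, col],
                 sd = recon$sd_stack[, row, col], epoch = recon$epoch,
                 flag = recon$flags[row, col]),
            class = "gpr_prediction")
}

#' Training-cost summary of a reconstruction mode
#'
#' Counts the optimiser runs and covariance factorisations a mode incurs on a
#' given stack, without running any numerics: per-pixel mode performs one
#' marginal-likelihood optimisation (and one factorisation) per trainable
#' pixel; fixed-theta modes perform zero optimisations and one factorisation
#' per distinct (theta, valid-pattern) pair. This cost model is what makes
#' precalculated hyperparameters orders of magnitude faster at scene scale.
#'
#' @param stack A [raster_stack()].
#' @param mode `"per_pixel"`, `"fixed"`, `"global"`, or `"per_crop"`.
#' @param crop_map Needed for `"per_crop"` (distinct thetas per class).
#' @param min_obs Minimum valid observations per pixel.
#' @return List with `optimizations`, `factorizations`, `trainable_pixels`.
#' @export
count_training_ops <- function(stack, mode, crop_map = NULL, min_obs = 4L) {
  stopifnot(inherits(stack, "raster_stack"))
  H <- dim(stack$data)[2]; W <- dim(stack$data)[3]
  vm <- stack$valid_mask & is.finite(stack$data)
  nv <- apply(vm, c(2, 3), sum)
  trainable <- nv >= min_obs
  if (mode == "per_pixel")
    return(list(optimizations = sum(trainable), factorizations = sum(trainable),
                trainable_pixels = sum(trainable)))
  keys <- character(0)
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (!trainable[r, c]) next
    tk <- if (mode == "per_crop" && !is.null(crop_map))
      as.character(crop_map$labels[r, c]) else "fixed"
    keys <- c(keys, paste0(tk, "|", paste(which(vm[, r, c]), collapse = ",")))
  }
  list(optimizations = 0L, factorizations = length(unique(keys)),
       trainable_pixels = sum(trainable))
}
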