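#' Pooled hyperparameter set
#'
#' Holds per-pixel trained hyperparameters together with their per-crop and
#' global (all-pixel) averages. Averages are unweighted arithmetic means of
#' the log triples: the global entry is pixel-weighted (mean over all trained
#' pixels), not a mean of the crop means — with unbalanced classes the two
#' differ.
#'
#' @param per_pixel Data frame with columns `row`, `col`, `class`,
#'   `log_inv_l`, `log_sigma_f`, `log_sigma_n`, `lml`.
#' @param per_crop Named list of [hyperparams()] (class name -> theta).
#' @param global A [hyperparams()].
#' @param provenance List of bookkeeping fields (seed, n_parcels, ...).
#' @param epoch Epoch date.
#' @return An object of class `theta_set`.
#' @export
theta_set <- function(per_pixel = NULL, per_crop = list(), global = NULL,
                      provenance = list(), epoch = as.Date("2016-01-01")) {
  stopifnot(is.list(per_crop),
            is.null(global) || inherits(global, "gpr_theta"))
  structure(list(per_pixel = per_pixel, per_crop = per_crop, global = global,
                 provenance = provenance, epoch = as.Date(epoch)),
            class = "theta_set")
}

#' @export
print.theta_set <- function(x, ...) {
  cat(sprintf("<theta_set> %d crop classes%s%s\n", length(x$per_crop),
              if (!is.null(x$global)) ", global average" else "",
              if (!is.null(x$per_pixel))
                sprintf(", %d per-pixel fits", nrow(x$per_pixel)) else ""))
  invisible(x)
}

# 4-connected components of a logical mask; returns an integer matrix of
# component labels (0 outside the mask). Scanline flood fill.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  idx_of <- function(r, c) (c - 1L) * H + r
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((i - 1L) %% H) + 1L; c <- ((i - 1L) %/% H) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= H && d[2] >= 1L && d[2] <= W) {
          j <- idx_of(d[1], d[2])
          if (mask[j] && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

#' Sample training parcels per crop class
#'
#' For each crop class, draws up to `n_parcels` parcels with at least
#' `min_pixels` pixels, without replacement. Parcels come from the map's
#' parcel-id raster when present, otherwise from 4-connected components of
#' same-class pixels. Classes short of eligible parcels return all of them
#' with a warning; classes with none return an empty set with a warning.
#'
#' @param map A [crop_map()].
#' @param n_parcels Parcels per class (default 100).
#' @param min_pixels Minimum parcel size in pixels (default 50).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Named list (class name -> data frame with columns `row`, `col`,
#'   `parcel`).
#' @export
sample_parcels <- function(map, n_parcels = 100L, min_pixels = 50L, seed = 1L) {
  stopifnot(inherits(map, "crop_map"))
  ids <- sort(unique(map$labels[map$labels != 0L]))
  out <- stats::setNames(vector("list", length(ids)),
                         unname(map$legend[as.character(ids)]))
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(ids)) {
      cls <- ids[k]
      in_class <- map$labels == cls
      pid <- if (!is.null(map$parcel_ids)) {
        p <- map$parcel_ids
        p[!in_class] <- 0L
        p
      } else {
        label_components(in_class)
      }
      sizes <- table(pid[pid != 0L])
      eligible <- as.integer(names(sizes)[sizes >= min_pixels])
      nm <- names(out)[k]
      if (length(eligible) == 0L) {
        warning(sprintf("class '%s': no parcels with >= %d pixels", nm, min_pixels))
        out[[k]] <- data.frame(row = integer(), col = integer(), parcel = integer())
        next
      }
      if (length(eligible) < n_parcels)
        warning(sprintf("class '%s': only %d eligible parcels (requested %d)",
                        nm, length(eligible), n_parcels))
      chosen <- if (length(eligible) <= n_parcels) eligible else
        sample(eligible, n_parcels)
      sel <- which(matrix(pid %in% chosen, nrow(pid), ncol(pid)), arr.ind = TRUE)
      out[[k]] <- data.frame(row = sel[, 1], col = sel[, 2],
                             parcel = pid[sel])
    }
  })
  out
}

#' Train per-pixel hyperparameters over selected pixels
#'
#' Runs [train_hyperparameters()] on each listed pixel of the stack. Pixels
#' with too few valid acquisitions or failed training are recorded with `NA`
#' hyperparameters, not fatal; a warning is raised if more than half fail.
#'
#' @param stack A [raster_stack()].
#' @param pixels Data frame with columns `row`, `col` and optionally `class`.
#' @param seed Base seed; pixel i trains with seed `seed + i` so the run is
#'   deterministic yet restarts differ across pixels.
#' @param ... Passed to [train_hyperparameters()] (`n_restarts`, `prior_box`,
#'   `min_obs`, ...).
#' @return Data frame: `row`, `col`, `class`, `log_inv_l`, `log_sigma_f`,
#'   `log_sigma_n`, `lml`, `ok`.
#' @export
train_per_pixel <- function(stack, pixels, seed = 1L, ...) {
  stopifnot(inherits(stack, "raster_stack"), is.data.frame(pixels),
            all(c("row", "col") %in% names(pixels)))
  cls <- if ("class" %in% names(pixels)) as.character(pixels$class)
         else rep(NA_character_, nrow(pixels))
  res <- vector("list", nrow(pixels))
  for (i in seq_len(nrow(pixels))) {
    ts <- pixel_series(stack, pixels$row[i], pixels$col[i])
    tr <- tryCatch(train_hyperparameters(ts, seed = as.integer(seed) + i, ...),
                   error = function(e) NULL)
    res[[i]] <- if (is.null(tr)) {
      data.frame(row = pixels$row[i], col = pixels$col[i], class = cls[i],
                 log_inv_l = NA_real_, log_sigma_f = NA_real_,
                 log_sigma_n = NA_real_, lml = NA_real_, ok = FALSE)
    } else {
      data.frame(row = pixels$row[i], col = pixels$col[i], class = cls[i],
                 log_inv_l = tr$theta$log_inv_l,
                 log_sigma_f = tr$theta$log_sigma_f,
                 log_sigma_n = tr$theta$log_sigma_n,
                 lml = tr$lml, ok = TRUE)
    }
  }
  out <- do.call(rbind, res)
  if (nrow(out) > 0 && mean(out$ok) < 0.5)
    warning(sprintf("per-pixel training failed for %.0f%% of pixels",
                    100 * (1 - mean(out$ok))))
  out
}

#' Average per-pixel hyperparameters per crop and globally
#'
#' Unweighted arithmetic mean of the log triples within each crop class, plus
#' a global mean over all trained pixels (pixel-weighted: every pixel counts
#' once, so class imbalance carries into the global average). Failed pixels
#' (`ok == FALSE` or `NA` entries) are excluded, never imputed. Empty groups
#' are omitted with a warning.
#'
#' @param per_pixel Data frame as returned by [train_per_pixel()].
#' @param provenance Optional bookkeeping list stored in the result.
#' @param epoch Epoch date.
#' @return A [theta_set()].
#' @export
average_hyperparameters <- function(per_pixel, provenance = list(),
                                    epoch = as.Date("2016-01-01")) {
  stopifnot(is.data.frame(per_pixel),
            all(c("class", "log_inv_l", "log_sigma_f", "log_sigma_n") %in%
                  names(per_pixel)))
  ok <- if ("ok" %in% names(per_pixel)) per_pixel$ok else TRUE
  ok <- ok & is.finite(per_pixel$log_inv_l) &
    is.finite(per_pixel$log_sigma_f) & is.finite(per_pixel$log_sigma_n)
  good <- per_pixel[ok, , drop = FALSE]
  if (nrow(good) == 0L)
    stop(errorCondition("no successfully trained pixels to average",
                        class = c("phenofill_insufficient_data", "error", "condition")))
  per_crop <- list()
  for (cl in unique(good$class)) {
    g <- good[good$class == cl, , drop = FALSE]
    per_crop[[cl]] <- hyperparams(mean(g$log_inv_l), mean(g$log_sigma_f),
                                  mean(g$log_sigma_n))
  }
  requested <- unique(per_pixel$class)
  missing <- setdiff(requested[!is.na(requested)], names(per_crop))
  if (length(missing))
    warning(sprintf("no trained pixels for class(es): %s; omitted",
                    paste(missing, collapse = ", ")))
  theta_set(per_pixel = per_pixel, per_crop = per_crop,
            global = hyperparams(mean(good$log_inv_l), mean(good$log_sigma_f),
                                 mean(good$log_sigma_n)),
            provenance = provenance, epoch = epoch)
}

#' Read/write a pooled hyperparameter set as JSON
#'
#' Layout: `{"per_crop": {"wheat": {...}, ...}, "global": {...}, "epoch":
#' "...", "provenance": {...}}`; each theta is the log triple.
#'
#' @param ts A [theta_set()].
#' @param path JSON path.
#' @export
write_theta_set <- function(ts, path) {
  stopifnot(inherits(ts, "theta_set"))
  to_j <- function(th) list(log_inv_l = th$log_inv_l,
                            log_sigma_f = th$log_sigma_f,
                            log_sigma_n = th$log_sigma_n)
  jsonlite::write_json(
    list(per_crop = lapply(ts$per_crop, to_j),
         global = if (!is.null(ts$global)) to_j(ts$global),
         epoch = format(ts$epoch), provenance = ts$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_theta_set
#' @export
read_theta_set <- function(path) {
  j <- jsonlite::read_json(path)
  from_j <- function(x) hyperparams(x$log_inv_l, x$log_sigma_f, x$log_sigma_n)
  theta_set(per_crop = lapply(j$per_crop, from_j),
            global = if (!is.null(j$global)) from_j(j$global),
            provenance = if (!is.null(j$provenance)) j$provenance else list(),
            epoch = if (!is.null(j$epoch)) as.Date(j$epoch) else as.Date("2016-01-01"))
}
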