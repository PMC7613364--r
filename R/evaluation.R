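#' Root mean square error between two series
#'
#' `sqrt(mean((a - b)^2))` over jointly finite points.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmse <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop(errorCondition("series lengths differ",
                        class = c("phenofill_invalid_input", "error", "condition")))
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok))
    stop(errorCondition("no jointly finite values",
                        class = c("phenofill_undefined_result", "error", "condition")))
  sqrt(mean((a[ok] - b[ok])^2))
}

#' RMSE as a percentage of the reference dynamic range
#'
#' `100 * rmse / (max(reference) - min(reference))` — the variation-percent
#' statistic used to express reconstruction differences relative to the
#' reference reconstruction's dynamic range.
#'
#' @param rmse_value Non-negative RMSE.
#' @param reference Numeric reference series (its finite range is used).
#' @return Percentage (>= 0).
#' @export
variation_percent <- function(rmse_value, reference) {
  reference <- reference[is.finite(reference)]
  rng <- if (length(reference)) max(reference) - min(reference) else 0
  if (rng <= 0)
    stop(errorCondition("reference range is zero; variation-percent undefined",
                        class = c("phenofill_undefined_result", "error", "condition")))
  100 * rmse_value / rng
}

#' Mean per-pixel temporal correlation between two reconstructions
#'
#' Pearson correlation over time per pixel, averaged per crop class.
#' Constant-in-time pixels (undefined correlation) are excluded and counted.
#'
#' @param recon_a,recon_b `recon_result`s (or plain `T x H x W` arrays) on the
#'   same grid.
#' @param crop_map Optional [crop_map()]; without it one class `"all"` is
#'   reported.
#' @return Data frame: `class`, `mean_r`, `n_pixels`, `n_excluded`.
#' @export
mean_pixel_correlation <- function(recon_a, recon_b, crop_map = NULL) {
  A <- if (inherits(recon_a, "recon_result")) recon_a$mean_stack else recon_a
  B <- if (inherits(recon_b, "recon_result")) recon_b$mean_stack else recon_b
  stopifnot(all(dim(A) == dim(B)))
  H <- dim(A)[2]; W <- dim(A)[3]
  cls <- if (is.null(crop_map)) matrix("all", H, W)
  else matrix(ifelse(crop_map$labels == 0L, NA_character_,
                     unname(crop_map$legend[as.character(crop_map$labels)])),
              H, W)
  rows <- list()
  for (cl in sort(unique(stats::na.omit(as.vector(cls))))) {
    rs <- numeric(0); nex <- 0L
    for (i in which(cls == cl)) {
      r <- ((i - 1L) %% H) + 1L; c <- ((i - 1L) %/% H) + 1L
      a <- A[, r, c]; b <- B[, r, c]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 2L) { nex <- nex + 1L; next }
      if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) { nex <- nex + 1L; next }
      rs <- c(rs, stats::cor(a[ok], b[ok]))
    }
    rows[[cl]] <- data.frame(class = cl, mean_r = mean(rs),
                             n_pixels = length(rs), n_excluded = nex)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean absolute deviation of paired phenology metrics
#'
#' Matches season records between two parameterisations on (pixel, season
#' slot) — nearest day-of-maximum within the same calendar year, pairs
#' farther apart than `max_dom_gap` days dropped — and reports the mean and
#' standard deviation of the absolute differences per metric.
#'
#' @param metrics_a,metrics_b Phenology record data frames (from
#'   [phenology_maps()]`$records` or [extract_phenology()] with `row`/`col`).
#' @param metrics Metric columns to compare.
#' @param max_dom_gap Maximum DOM separation for a valid match (days).
#' @return Data frame: `metric`, `mad`, `sd_ad`, `n_pairs`, `n_unmatched`.
#' @export
mad_phenology <- function(metrics_a, metrics_b,
                          metrics = c("sos", "eos", "los", "dom", "max_value",
                                      "amplitude", "blue_area", "green_area"),
                          max_dom_gap = 90) {
  need <- c("row", "col", "year", "dom")
  stopifnot(all(need %in% names(metrics_a)), all(need %in% names(metrics_b)))
  a <- metrics_a[metrics_a$flag == "ok", , drop = FALSE]
  b <- metrics_b[metrics_b$flag == "ok", , drop = FALSE]
  keyb <- paste(b$row, b$col, b$year)
  pairs_a <- integer(0); pairs_b <- integer(0)
  used_b <- rep(FALSE, nrow(b))
  n_unmatched <- 0L
  for (i in seq_len(nrow(a))) {
    cand <- which(keyb == paste(a$row[i], a$col[i], a$year[i]) & !used_b)
    if (!length(cand)) { n_unmatched <- n_unmatched + 1L; next }
    j <- cand[which.min(abs(b$dom[cand] - a$dom[i]))]
    if (abs(b$dom[j] - a$dom[i]) > max_dom_gap) {
      n_unmatched <- n_unmatched + 1L; next
    }
    used_b[j] <- TRUE
    pairs_a <- c(pairs_a, i); pairs_b <- c(pairs_b, j)
  }
  n_unmatched <- n_unmatched + sum(!used_b)
  if (!length(pairs_a))
    stop(errorCondition("no matched season pairs",
                        class = c("phenofill_undefined_result", "error", "condition")))
  rows <- lapply(metrics, function(m) {
    d <- abs(a[[m]][pairs_a] - b[[m]][pairs_b])
    d <- d[is.finite(d)]
    data.frame(metric = m, mad = mean(d), sd_ad = stats::sd(d),
               n_pairs = length(d), n_unmatched = n_unmatched)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class comparison of two reconstructions
#'
#' The tabular comparison used to judge pooled against per-pixel
#' hyperparameters: per crop class, the mean over pixels of the per-pixel
#' RMSE between the two reconstructions, the variation-percent of that RMSE
#' relative to each pixel's reference dynamic range (reconstruction `a` is
#' the reference), and the mean per-pixel temporal correlation.
#'
#' @param recon_a Reference `recon_result` (e.g. per-pixel optimised).
#' @param recon_b Comparison `recon_result` (e.g. fixed global theta).
#' @param crop_map Optional [crop_map()] for per-class rows.
#' @return Data frame: `class`, `mean_rmse`, `variation_percent`, `mean_r`,
#'   `n_pixels`.
#' @export
compare_reconstructions <- function(recon_a, recon_b, crop_map = NULL) {
  A <- recon_a$mean_stack; B <- recon_b$mean_stack
  stopifnot(all(dim(A) == dim(B)))
  H <- dim(A)[2]; W <- dim(A)[3]
  cls <- if (is.null(crop_map)) matrix("all", H, W)
  else matrix(ifelse(crop_map$labels == 0L, NA_character_,
                     unname(crop_map$legend[as.character(crop_map$labels)])),
              H, W)
  corr <- mean_pixel_correlation(A, B, crop_map)
  rows <- list()
  for (cl in sort(unique(stats::na.omit(as.vector(cls))))) {
    rmses <- numeric(0); vps <- numeric(0)
    for (i in which(cls == cl)) {
      r <- ((i - 1L) %% H) + 1L; c <- ((i - 1L) %/% H) + 1L
      a <- A[, r, c]; b <- B[, r, c]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 2L) next
      e <- sqrt(mean((a[ok] - b[ok])^2))
      rng <- max(a[ok]) - min(a[ok])
      if (rng <= 0) next
      rmses <- c(rmses, e); vps <- c(vps, 100 * e / rng)
    }
    if (!length(rmses)) next
    rows[[cl]] <- data.frame(class = cl, mean_rmse = mean(rmses),
                             variation_percent = mean(vps),
                             n_pixels = length(rmses))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  merge(out, corr[, c("class", "mean_r")], by = "class", sort = TRUE)
}
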