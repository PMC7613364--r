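#' Detect growing seasons in a reconstructed series
#'
#' Scans a regular-grid series for local maxima whose topographic prominence
#' is at least `min_prominence` times the series' global range; each retained
#' peak is flanked by the deepest minima towards its neighbouring peaks
#' (series endpoints act as minima). The season base level is the mean of the
#' two flanking minimum values. Seasons whose width at 20% of their own
#' amplitude (the same level that later defines SOS/EOS) is shorter than
#' `min_season_length` days are discarded as spurious blips.
#'
#' @param series A `gpr_prediction` or any list with numeric `times` and
#'   `mean` on a regular grid (>= 3 points).
#' @param min_prominence Fraction of the global range (default 0.1).
#' @param min_season_length Minimum segment span in days (default 30).
#' @return Data frame of season segments: `left_time`, `left_value`,
#'   `peak_time`, `peak_value`, `right_time`, `right_value`, `base_level`,
#'   plus grid indices `left_idx`, `peak_idx`, `right_idx`. Zero rows for
#'   flat or peak-less series.
#' @export
detect_seasons <- function(series, min_prominence = 0.1,
                           min_season_length = 30) {
  t <- as.numeric(series$times); x <- as.numeric(series$mean)
  stopifnot(length(t) == length(x))
  keep <- is.finite(x)
  empty <- data.frame(left_time = numeric(), left_value = numeric(),
                      peak_time = numeric(), peak_value = numeric(),
                      right_time = numeric(), right_value = numeric(),
                      base_level = numeric(), left_idx = integer(),
                      peak_idx = integer(), right_idx = integer())
  if (sum(keep) < 3L || !all(keep)) return(empty)
  n <- length(x)
  rng <- max(x) - min(x)
  if (rng < 1e-9 * max(1, max(abs(x)))) return(empty)

  # interior local maxima (strict on at least one side)
  cand <- which(vapply(2:(n - 1), function(i)
    x[i] >= x[i - 1] && x[i] >= x[i + 1] &&
      (x[i] > x[i - 1] || x[i] > x[i + 1]), logical(1))) + 1L
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(i) {
    hl <- which(x[seq_len(i - 1)] > x[i])
    lo_l <- if (length(hl)) min(x[(max(hl) + 1):i]) else min(x[1:i])
    hr <- which(x[(i + 1):n] > x[i])
    lo_r <- if (length(hr)) min(x[i:(i + min(hr) - 1)]) else min(x[i:n])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  peaks <- cand[prom >= min_prominence * rng]
  if (!length(peaks)) return(empty)

  # flanking minima: deepest point between adjacent peaks / to the endpoints
  k <- length(peaks)
  left_idx <- integer(k); right_idx <- integer(k)
  for (j in seq_len(k)) {
    lo <- if (j == 1L) 1L else peaks[j - 1L]
    hi <- if (j == k) n else peaks[j + 1L]
    seg_l <- lo:peaks[j]
    left_idx[j] <- seg_l[which.min(x[seg_l])]
    seg_r <- peaks[j]:hi
    right_idx[j] <- seg_r[which.min(x[seg_r])]
  }
  out <- data.frame(left_time = t[left_idx], left_value = x[left_idx],
                    peak_time = t[peaks], peak_value = x[peaks],
                    right_time = t[right_idx], right_value = x[right_idx],
                    base_level = (x[left_idx] + x[right_idx]) / 2,
                    left_idx = left_idx, peak_idx = peaks,
                    right_idx = right_idx)
  width <- vapply(seq_len(nrow(out)), function(j) {
    level <- out$base_level[j] + 0.2 * (out$peak_value[j] - out$base_level[j])
    lo <- out$left_idx[j]:out$peak_idx[j]
    hi <- out$peak_idx[j]:out$right_idx[j]
    below_l <- lo[x[lo] <= level]
    below_r <- hi[x[hi] <= level]
    a <- if (length(below_l)) t[max(below_l)] else out$left_time[j]
    b <- if (length(below_r)) t[min(below_r)] else out$right_time[j]
    b - a
  }, numeric(1))
  out[width >= min_season_length, , drop = FALSE]
}

# linear-interpolated time where the segment x[i]..x[i+1] crosses level
cross_at <- function(t, x, i, level) {
  if (x[i + 1] == x[i]) return(t[i])
  t[i] + (level - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i])
}

# trapezoidal integral of y(t) over [a, b] with interpolated endpoints
trapz_between <- function(t, y, a, b) {
  if (b <= a) return(0)
  ya <- stats::approx(t, y, xout = a, rule = 2)$y
  yb <- stats::approx(t, y, xout = b, rule = 2)$y
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  yy <- c(ya, y[inside], yb)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Phenology indicators of one season
#'
#' The start of season (SOS) is where the rising limb crosses
#' `base_level + threshold_frac * amplitude` (last upward crossing before the
#' peak, located by linear interpolation between grid points); the end of
#' season (EOS) is the first downward crossing of the same level after the
#' peak. Day of maximum (DOM) is the grid argmax, length of season
#' LOS = EOS - SOS, amplitude = peak value - base level. The green area is
#' the trapezoidal integral of the curve above the base level between SOS and
#' EOS; the blue area is the integral of the curve itself (above zero) over
#' the same window, so lifting a series by a constant changes only the blue
#' area (by constant x LOS).
#'
#' @param segment One row of [detect_seasons()] output.
#' @param series The same series the segment came from.
#' @param threshold_frac Amplitude fraction defining SOS/EOS (default 0.20).
#'   At 0 the season degenerates to the flanking minima.
#' @return One-row data frame: `sos`, `eos`, `los`, `dom` (days),
#'   `max_value`, `amplitude` (descriptor units), `blue_area`, `green_area`
#'   (units x days), `flag` (`"ok"` or a reason for missing crossings).
#' @export
season_metrics <- function(segment, series, threshold_frac = 0.20) {
  t <- as.numeric(series$times); x <- as.numeric(series$mean)
  li <- segment$left_idx; pk <- segment$peak_idx; ri <- segment$right_idx
  base <- segment$base_level
  amp <- segment$peak_value - base
  miss <- function(reason)
    data.frame(sos = NA_real_, eos = NA_real_, los = NA_real_, dom = NA_real_,
               max_value = segment$peak_value, amplitude = amp,
               blue_area = NA_real_, green_area = NA_real_, flag = reason)
  if (threshold_frac == 0) {
    sos <- segment$left_time; eos <- segment$right_time
  } else {
    level <- base + threshold_frac * amp
    sos <- NA_real_
    if (pk > li)
      for (i in (pk - 1L):li)
        if (x[i] <= level && x[i + 1] > level) {
          sos <- cross_at(t, x, i, level); break
        }
    if (!is.finite(sos)) return(miss("no_rising_crossing"))
    eos <- NA_real_
    if (ri > pk)
      for (i in pk:(ri - 1L))
        if (x[i] >= level && x[i + 1] < level) {
          eos <- cross_at(t, x, i, level); break
        }
    if (!is.finite(eos)) return(miss("no_falling_crossing"))
  }
  blue <- trapz_between(t, x, sos, eos)
  green <- trapz_between(t, pmax(x - base, 0), sos, eos)
  data.frame(sos = sos, eos = eos, los = eos - sos, dom = segment$peak_time,
             max_value = segment$peak_value, amplitude = amp,
             blue_area = blue, green_area = green, flag = "ok")
}

#' All-season phenology of one series
#'
#' Convenience wrapper: [detect_seasons()] then [season_metrics()] per
#' segment, with each season assigned to the calendar year containing its
#' day of maximum.
#'
#' @inheritParams detect_seasons
#' @inheritParams season_metrics
#' @param epoch Epoch date used for the year assignment (taken from the
#'   series when present).
#' @return Data frame, one row per detected season, with `season` index and
#'   `year` in addition to the [season_metrics()] columns.
#' @export
extract_phenology <- function(series, threshold_frac = 0.20,
                              min_prominence = 0.1, min_season_length = 30,
                              epoch = NULL) {
  if (is.null(epoch)) epoch <- series$epoch
  if (is.null(epoch)) epoch <- as.Date("2016-01-01")
  segs <- detect_seasons(series, min_prominence, min_season_length)
  if (nrow(segs) == 0L)
    return(data.frame(season = integer(), year = integer(), sos = numeric(),
                      eos = numeric(), los = numeric(), dom = numeric(),
                      max_value = numeric(), amplitude = numeric(),
                      blue_area = numeric(), green_area = numeric(),
                      flag = character()))
  rows <- lapply(seq_len(nrow(segs)), function(j)
    season_metrics(segs[j, ], series, threshold_frac))
  out <- do.call(rbind, rows)
  out <- cbind(season = seq_len(nrow(out)),
               year = as.integer(format(as.Date(epoch) + out$dom, "%Y")),
               out)
  out
}

#' Per-pixel phenology metric maps
#'
#' Extracts seasons for every successfully reconstructed pixel and arranges
#' each indicator into raster layers, one layer per season slot (season index
#' or calendar year). Pixels with no detected season (or flagged in the
#' reconstruction) are nodata in every layer.
#'
#' @param recon A [reconstruct_stack()] result.
#' @param threshold_frac,min_prominence,min_season_length See
#'   [season_metrics()] and [detect_seasons()].
#' @param by Slot assignment: `"season"` (detection order) or `"year"`
#'   (calendar year of DOM).
#' @return List: `records` (data frame with `row`, `col`, `season`, `year`,
#'   `slot` and the metric columns), `maps` (named list of `H x W x n_slots`
#'   arrays per metric), `slots` (slot labels).
#' @export
phenology_maps <- function(recon, threshold_frac = 0.20, min_prominence = 0.1,
                           min_season_length = 30, by = c("season", "year")) {
  stopifnot(inherits(recon, "recon_result"))
  by <- match.arg(by)
  H <- dim(recon$mean_stack)[2]; W <- dim(recon$mean_stack)[3]
  recs <- vector("list", H * W)
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (recon$flags[r, c] != "ok") next
    ph <- extract_phenology(recon_series(recon, r, c), threshold_frac,
                            min_prominence, min_season_length,
                            epoch = recon$epoch)
    if (nrow(ph) == 0L) next
    recs[[(c - 1L) * H + r]] <- cbind(row = r, col = c, ph)
  }
  records <- do.call(rbind, recs)
  metrics <- c("sos", "eos", "los", "dom", "max_value", "amplitude",
               "blue_area", "green_area")
  if (is.null(records)) {
    return(list(records = data.frame(), maps = list(), slots = integer()))
  }
  records$slot <- if (by == "year") records$year else records$season
  slots <- sort(unique(records$slot))
  maps <- lapply(metrics, function(m) {
    a <- array(NA_real_, c(H, W, length(slots)))
    for (s in seq_along(slots)) {
      rs <- records[records$slot == slots[s] & records$flag == "ok", ]
      a[cbind(rs$row, rs$col, s)] <- rs[[m]]
    }
    a
  })
  list(records = records, maps = stats::setNames(maps, metrics), slots = slots)
}
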