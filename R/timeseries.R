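#' Single-pixel observation series
#'
#' One pixel's irregularly sampled observations: acquisition times in days
#' since an epoch, descriptor values (e.g. LAI in m2/m2), and a validity mask
#' marking cloud-free usable acquisitions. Invalid entries are retained (for
#' bookkeeping) but never enter a fit.
#'
#' @param times Numeric vector, days since `epoch`; strictly increasing after
#'   masking.
#' @param values Numeric vector, same length.
#' @param valid Logical vector, same length; defaults to finite values.
#' @param epoch Epoch date the times count from.
#' @return An object of class `pixel_ts`.
#' @examples
#' ts <- time_series(c(0, 10, 20), c(0.5, 1.2, NA), c(TRUE, TRUE, FALSE))
#' valid_times(ts)
#' @export
time_series <- function(times, values, valid = NULL, epoch = as.Date("2016-01-01")) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- as.logical(valid) & is.finite(times) & is.finite(values)
  if (length(valid) != length(times))
    stop("valid mask length mismatch", call. = FALSE)
  tv <- times[valid]
  if (anyDuplicated(tv) || is.unsorted(tv, strictly = TRUE))
    stop("valid times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values, valid = valid,
                 epoch = as.Date(epoch)),
            class = "pixel_ts")
}

#' @export
print.pixel_ts <- function(x, ...) {
  cat(sprintf("<pixel_ts> %d obs (%d valid), days %.1f..%.1f since %s\n",
              length(x$times), sum(x$valid),
              min(x$times), max(x$times), format(x$epoch)))
  invisible(x)
}

#' @rdname time_series
#' @param ts A `pixel_ts`.
#' @export
valid_times <- function(ts) ts$times[ts$valid]

#' @rdname time_series
#' @export
valid_values <- function(ts) ts$values[ts$valid]

#' @rdname time_series
#' @export
n_valid <- function(ts) sum(ts$valid)

#' Read/write a single-pixel series as CSV
#'
#' Columns: `date` (ISO-8601), `value` (float), optional `qa` (1 = usable,
#' 0 = flagged). Times are converted to days since `epoch`.
#'
#' @param path CSV path.
#' @param epoch Epoch date.
#' @return `read_pixel_csv` returns a `pixel_ts`.
#' @export
read_pixel_csv <- function(path, epoch = as.Date("2016-01-01")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(d)))
    stop("pixel CSV needs 'date' and 'value' columns", call. = FALSE)
  epoch <- as.Date(epoch)
  tm <- as.numeric(as.Date(d$date) - epoch)
  qa <- if ("qa" %in% names(d)) d$qa == 1 else rep(TRUE, nrow(d))
  o <- order(tm)
  time_series(tm[o], d$value[o], qa[o] & is.finite(d$value[o]), epoch = epoch)
}

#' @rdname read_pixel_csv
#' @param ts A `pixel_ts`.
#' @export
write_pixel_csv <- function(ts, path) {
  utils::write.csv(
    data.frame(date = format(ts$epoch + ts$times), value = ts$values,
               qa = as.integer(ts$valid)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
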