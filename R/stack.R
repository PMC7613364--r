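#' Image time-series cube
#'
#' A `T x H x W` data cube of a vegetation descriptor with acquisition dates,
#' a validity (cloud/nodata) mask and opaque georeferencing metadata. Times
#' are carried as days since `epoch`.
#'
#' @param data Numeric `T x H x W` array.
#' @param dates `Date` vector of length `T`, strictly increasing.
#' @param valid_mask Logical array, same shape; defaults to finite data.
#' @param epoch Epoch date; defaults to the first acquisition's year start.
#' @param geo List of georeferencing metadata (crs, affine transform); carried
#'   through unchanged.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(data, dates, valid_mask = NULL, epoch = NULL,
                         geo = list()) {
  data <- unclass(data)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  dates <- as.Date(dates)
  if (length(dates) != dim(data)[1])
    stop("length(dates) must equal dim(data)[1]", call. = FALSE)
  if (is.unsorted(as.numeric(dates), strictly = TRUE))
    stop("dates must be strictly increasing", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- is.finite(data) & !is.na(data)
  valid_mask <- array(as.logical(valid_mask), dim(data))
  valid_mask[!is.finite(data)] <- FALSE
  if (is.null(epoch)) epoch <- as.Date(format(dates[1], "%Y-01-01"))
  structure(list(data = data, dates = dates, valid_mask = valid_mask,
                 epoch = as.Date(epoch), geo = geo),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raster_stack> %d acquisitions x %d x %d px, %s..%s, %.1f%% valid\n",
              d[1], d[2], d[3], format(x$dates[1]), format(x$dates[d[1]]),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' @rdname raster_stack
#' @param stack A `raster_stack`.
#' @return `stack_times` returns acquisition times in days since the epoch.
#' @export
stack_times <- function(stack) as.numeric(stack$dates - stack$epoch)

#' @rdname raster_stack
#' @param row,col Pixel indices (1-based, row = y from top).
#' @return `pixel_series` returns the pixel's [time_series()].
#' @export
pixel_series <- function(stack, row, col) {
  time_series(stack_times(stack), stack$data[, row, col],
              stack$valid_mask[, row, col], epoch = stack$epoch)
}

# ---- file I/O: multi-plane 32-bit-float TIFF + sidecar JSON -----------------
# TIFF planes store values scaled to [0,1]; gain/offset live in the sidecar.

scale_to_unit <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  list(offset = rng[1], gain = rng[2] - rng[1],
       scaled = (x - rng[1]) / (rng[2] - rng[1]))
}

#' Read/write an image time-series stack
#'
#' On-disk layout: `<prefix>.tif` (one 32-bit-float plane per acquisition,
#' values scaled to `[0,1]`), `<prefix>_mask.tif` (validity planes) and
#' `<prefix>.json` (dates, epoch, scaling gain/offset, geo metadata).
#'
#' @param stack A [raster_stack()].
#' @param prefix Path prefix (without extension).
#' @return `read_stack` returns a [raster_stack()]; values round-trip at
#'   32-bit-float precision relative to the cube's dynamic range.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "raster_stack"))
  d <- stack$data
  d[!stack$valid_mask] <- NA_real_
  sc <- scale_to_unit(d)
  planes <- lapply(seq_len(dim(d)[1]), function(k) {
    m <- sc$scaled[k, , ]
    m[!is.finite(m)] <- 0
    m
  })
  tiff::writeTIFF(planes, paste0(prefix, ".tif"), bits.per.sample = 32)
  tiff::writeTIFF(lapply(seq_len(dim(d)[1]),
                         function(k) stack$valid_mask[k, , ] * 1),
                  paste0(prefix, "_mask.tif"), bits.per.sample = 8)
  jsonlite::write_json(
    list(dates = format(stack$dates), epoch = format(stack$epoch),
         times = as.numeric(stack$dates - stack$epoch),
         gain = sc$gain, offset = sc$offset, geo = stack$geo,
         shape = dim(d)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  masks <- tiff::readTIFF(paste0(prefix, "_mask.tif"), all = TRUE)
  Tn <- length(planes)
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  data <- array(NA_real_, c(Tn, H, W))
  valid <- array(FALSE, c(Tn, H, W))
  for (k in seq_len(Tn)) {
    data[k, , ] <- planes[[k]] * meta$gain + meta$offset
    valid[k, , ] <- masks[[k]] > 0.5
  }
  data[!valid] <- NA_real_
  dates <- if (!is.null(meta$times)) as.Date(meta$epoch) + meta$times
           else as.Date(meta$dates)
  raster_stack(data, dates = dates, valid_mask = valid,
               epoch = as.Date(meta$epoch), geo = as.list(meta$geo))
}

#' Crop-class map
#'
#' Integer class raster with a legend and an optional parcel-id raster. Label
#' 0 is reserved for unclassified / non-crop pixels.
#'
#' @param labels Integer `H x W` matrix.
#' @param legend Named character vector or list mapping class id (as name) to
#'   class name; must cover every nonzero label present.
#' @param parcel_ids Optional integer `H x W` matrix of parcel identifiers.
#' @return An object of class `crop_map`.
#' @export
crop_map <- function(labels, legend, parcel_ids = NULL) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  present <- sort(unique(labels[labels != 0L]))
  legend <- stats::setNames(as.character(unlist(legend)), names(legend))
  if (!all(as.character(present) %in% names(legend)))
    stop("legend must cover all nonzero labels present", call. = FALSE)
  if (!is.null(parcel_ids)) {
    parcel_ids <- matrix(as.integer(parcel_ids), nrow(labels), ncol(labels))
    stopifnot(all(dim(parcel_ids) == dim(labels)))
  }
  structure(list(labels = labels, legend = legend, parcel_ids = parcel_ids),
            class = "crop_map")
}

#' @export
print.crop_map <- function(x, ...) {
  cat(sprintf("<crop_map> %d x %d px, %d classes%s\n",
              nrow(x$labels), ncol(x$labels), length(x$legend),
              if (is.null(x$parcel_ids)) "" else ", with parcel ids"))
  invisible(x)
}

#' @rdname crop_map
#' @param map A `crop_map`.
#' @param id Integer class id.
#' @export
class_name <- function(map, id) unname(map$legend[as.character(id)])

#' Read/write a crop map
#'
#' `<prefix>.tif` stores the label raster (and a second plane with parcel ids
#' when present) as scaled 32-bit floats; `<prefix>.json` stores the legend
#' and scaling.
#'
#' @param map A [crop_map()].
#' @param prefix Path prefix.
#' @export
write_crop_map <- function(map, prefix) {
  planes <- list(map$labels)
  if (!is.null(map$parcel_ids)) planes <- c(planes, list(map$parcel_ids))
  mx <- max(1L, max(unlist(lapply(planes, max))))
  tiff::writeTIFF(lapply(planes, function(p) p / mx),
                  paste0(prefix, ".tif"), bits.per.sample = 32)
  jsonlite::write_json(
    list(legend = as.list(map$legend), gain = mx,
         has_parcels = !is.null(map$parcel_ids)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_crop_map
#' @export
read_crop_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  labels <- matrix(as.integer(round(planes[[1]] * meta$gain)),
                   nrow(planes[[1]]), ncol(planes[[1]]))
  parcels <- if (isTRUE(meta$has_parcels))
    matrix(as.integer(round(planes[[2]] * meta$gain)),
           nrow(planes[[2]]), ncol(planes[[2]]))
  crop_map(labels, legend = unlist(meta$legend), parcel_ids = parcels)
}
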