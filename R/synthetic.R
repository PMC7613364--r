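#' Seasonal double-logistic crop curve
#'
#' Parameters of the standard double-logistic phenology curve used by the
#' synthetic scene generator. The two inflection centres are placed so that
#' the curve's 20%-of-amplitude crossings (counted from the base level) fall
#' exactly at `sos` and `eos` — the closed-form crossings of the rising and
#' falling logistic limbs, so the generated truth is analytically checkable.
#'
#' @param base Background descriptor level (e.g. winter LAI).
#' @param amplitude Seasonal amplitude above `base`.
#' @param sos,eos True start/end of season in day-of-year (20% crossings).
#' @param growth_rate,senescence_rate Logistic rates (1/days), > 0.
#' @param seasons_per_year Number of seasons per calendar year (default 1).
#' @return An object of class `crop_curve`.
#' @export
crop_curve_params <- function(base, amplitude, sos, eos,
                              growth_rate = 0.10, senescence_rate = 0.08,
                              seasons_per_year = 1L) {
  base <- unname(as.numeric(base)); amplitude <- unname(as.numeric(amplitude))
  sos <- unname(as.numeric(sos)); eos <- unname(as.numeric(eos))
  growth_rate <- unname(as.numeric(growth_rate))
  senescence_rate <- unname(as.numeric(senescence_rate))
  stopifnot(amplitude > 0, sos < eos, growth_rate > 0, senescence_rate > 0,
            seasons_per_year >= 1L)
  structure(list(base = base, amplitude = amplitude, sos = sos, eos = eos,
                 growth_rate = growth_rate, senescence_rate = senescence_rate,
                 seasons_per_year = as.integer(seasons_per_year)),
            class = "crop_curve")
}

# Inflection centres from the 20% crossing placement:
# rising limb hits fraction q at t = s1 + log(q/(1-q))/a, so with
# s1 = sos + log(4)/a the q = 0.2 crossing is exactly sos (and symmetrically
# s2 = eos - log(4)/b for the falling limb).
curve_centers <- function(p) {
  c(s1 = p$sos + log(4) / p$growth_rate,
    s2 = p$eos - log(4) / p$senescence_rate)
}

#' @rdname crop_curve_params
#' @param p A `crop_curve`.
#' @param q Amplitude fraction in (0, 1).
#' @return `curve_crossings` returns the closed-form times (day-of-year) at
#'   which each limb crosses `base + q * amplitude`.
#' @export
curve_crossings <- function(p, q = 0.20) {
  stopifnot(inherits(p, "crop_curve"), q > 0, q < 1)
  ct <- curve_centers(p)
  c(rise = unname(ct["s1"] + log(q / (1 - q)) / p$growth_rate),
    fall = unname(ct["s2"] - log(q / (1 - q)) / p$senescence_rate))
}

#' Evaluate a double-logistic crop curve
#'
#' \deqn{f(t) = b + A\left[\frac{1}{1+e^{-a(t-s_1)}} -
#'   \frac{1}{1+e^{-c(t-s_2)}}\right]}
#' summed over one pulse per season. `t` is in days since the epoch of the
#' scene; `year_offsets` shifts the pulse to successive years (day-of-year
#' parameterisation plus 365-day year offsets).
#'
#' @param t Numeric times (days since epoch).
#' @param p A [crop_curve_params()] object.
#' @param year_offsets Numeric vector of day offsets, one pulse per entry
#'   (default a single pulse at offset 0).
#' @return Numeric curve values, same length as `t`.
#' @export
double_logistic <- function(t, p, year_offsets = 0) {
  stopifnot(inherits(p, "crop_curve"))
  ct <- curve_centers(p)
  v <- rep(p$base, length(t))
  for (off in year_offsets) {
    v <- v + p$amplitude *
      (stats::plogis(p$growth_rate * (t - (ct["s1"] + off))) -
         stats::plogis(p$senescence_rate * (t - (ct["s2"] + off))))
  }
  as.numeric(v)
}

#' Default crop curve library
#'
#' Nine crop classes with distinct seasonal curves — winter cereals and rape
#' with early green-up, summer crops (corn, sunflower, beet, potato) peaking
#' mid-year, pea and a long-season alfalfa — with realistic LAI bases (0.2-0.5
#' m2/m2) and amplitudes (2-5 m2/m2) for a dryland agricultural mosaic.
#'
#' @return Named list of [crop_curve_params()].
#' @export
default_crop_library <- function() {
  list(
    wheat     = crop_curve_params(0.30, 2.5,  60, 180, 0.10, 0.09),
    corn      = crop_curve_params(0.20, 4.5, 150, 280, 0.11, 0.09),
    barley    = crop_curve_params(0.30, 2.2,  55, 170, 0.10, 0.09),
    sunflower = crop_curve_params(0.20, 2.8, 140, 260, 0.10, 0.08),
    rape      = crop_curve_params(0.30, 3.5,  45, 175, 0.09, 0.08),
    pea       = crop_curve_params(0.20, 2.0,  70, 180, 0.10, 0.09),
    alfalfa   = crop_curve_params(0.50, 2.0,  80, 300, 0.07, 0.06),
    beet      = crop_curve_params(0.20, 4.0, 130, 290, 0.09, 0.08),
    potato    = crop_curve_params(0.20, 4.8, 145, 265, 0.11, 0.10))
}

#' Synthetic scene configuration
#'
#' Defines a multi-crop scene emulating a decametric satellite collection
#' over cropland: a parcel mosaic of crop classes, a quasi-regular revisit
#' schedule with day jitter, spatially correlated cloud gaps, additive
#' Gaussian observation noise and small per-pixel parameter perturbations.
#'
#' @param height,width Scene size in pixels.
#' @param parcel_px Side length of the square parcels (pixels).
#' @param classes Named list of [crop_curve_params()].
#' @param start,end First/last acquisition dates.
#' @param revisit_days Nominal revisit interval (days).
#' @param jitter_days Uniform acquisition-day jitter half-width.
#' @param cloud_prob Expected per-acquisition masked-area fraction in `[0,1)`;
#'   gaps are correlated blobs, not i.i.d. pixels.
#' @param noise_sd Additive Gaussian noise standard deviation (descriptor
#'   units).
#' @param perturb List with `sos_sd`, `eos_sd` (days), `amp_frac_sd`
#'   (multiplicative), `base_sd` (descriptor units) of the per-pixel
#'   perturbations.
#' @param seed Integer seed; the scene is fully determined by it (base R
#'   Mersenne-Twister stream).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 60L, width = 60L, parcel_px = 10L,
                         classes = default_crop_library(),
                         start = as.Date("2016-01-01"),
                         end = as.Date("2017-12-31"),
                         revisit_days = 5, jitter_days = 1,
                         cloud_prob = 0.25, noise_sd = 0.10,
                         perturb = list(sos_sd = 3, eos_sd = 3,
                                        amp_frac_sd = 0.05, base_sd = 0.05),
                         seed = 42L) {
  stopifnot(height >= 1, width >= 1, parcel_px >= 1,
            cloud_prob >= 0, cloud_prob < 1, noise_sd >= 0,
            length(classes) >= 1, !is.null(names(classes)))
  start <- as.Date(start); end <- as.Date(end)
  if (as.numeric(end - start) < 365)
    stop(errorCondition("scene schedule must span at least one full season",
                        class = c("phenofill_config", "error", "condition")))
  structure(list(height = as.integer(height), width = as.integer(width),
                 parcel_px = as.integer(parcel_px), classes = classes,
                 start = start, end = end, revisit_days = revisit_days,
                 jitter_days = jitter_days, cloud_prob = cloud_prob,
                 noise_sd = noise_sd, perturb = perturb,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Spatially correlated cloud gaps: a boolean model of random discs whose
# intensity is calibrated so the expected covered fraction equals cloud_prob.
cloud_mask_one <- function(H, W, cloud_prob, rmin, rmax) {
  if (cloud_prob <= 0) return(matrix(FALSE, H, W))
  er2 <- (rmin^2 + rmin * rmax + rmax^2) / 3
  lambda0 <- -log(1 - cloud_prob) / (pi * er2)
  n <- stats::rpois(1, lambda0 * (H + 2 * rmax) * (W + 2 * rmax))
  m <- matrix(FALSE, H, W)
  if (n == 0) return(m)
  cy <- stats::runif(n, 0.5 - rmax, H + 0.5 + rmax)
  cx <- stats::runif(n, 0.5 - rmax, W + 0.5 + rmax)
  r <- stats::runif(n, rmin, rmax)
  rowi <- row(m); coli <- col(m)
  for (k in seq_len(n))
    m <- m | ((rowi - cy[k])^2 + (coli - cx[k])^2 <= r[k]^2)
  m
}

#' Generate a synthetic multi-crop scene with known truth
#'
#' Builds the parcel mosaic, evaluates each pixel's (perturbed) crop curve on
#' the acquisition schedule, adds observation noise, and drops acquisitions
#' under spatially correlated cloud blobs. Returns the observed stack, the
#' crop map (with parcel ids) and ground-truth tables: the clean noise-free
#' cube and the per-pixel, per-season analytic phenology (20% crossings).
#'
#' @param config A [scene_config()].
#' @return List with elements `stack` ([raster_stack()]), `crop_map`
#'   ([crop_map()]), `truth` (list: `clean` T x H x W array, `phenology`
#'   data frame with columns row, col, class, season, sos, eos, amplitude,
#'   base, `params` per-pixel perturbed curve parameters).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$height; W <- config$width
  withr::with_seed(config$seed, {
    epoch <- config$start
    nominal <- seq(0, as.numeric(config$end - config$start), by = config$revisit_days)
    jit <- if (config$jitter_days > 0)
      stats::runif(length(nominal), -config$jitter_days, config$jitter_days) else 0
    times <- sort(nominal + jit)
    times <- times[!duplicated(round(times, 6))]
    Tn <- length(times)
    if (Tn < 2)
      stop(errorCondition("degenerate schedule: fewer than 2 acquisitions",
                          class = c("phenofill_config", "error", "condition")))

    # parcel mosaic: square blocks, classes assigned in shuffled round-robin
    pr <- ceiling(H / config$parcel_px); pc <- ceiling(W / config$parcel_px)
    np <- pr * pc
    cls_names <- names(config$classes)
    assign_cls <- sample(rep_len(seq_along(cls_names), np))
    parcel_of <- function(r, c)
      (ceiling(r / config$parcel_px) - 1L) * pc + ceiling(c / config$parcel_px)
    rowi <- matrix(rep(seq_len(H), W), H, W)
    coli <- matrix(rep(seq_len(W), each = H), H, W)
    parcel_ids <- matrix(parcel_of(rowi, coli), H, W)
    labels <- matrix(assign_cls[parcel_ids], H, W)

    years <- seq(0, by = 365,
                 length.out = max(1L, floor(as.numeric(config$end - config$start) / 365)))
    pb <- config$perturb

    clean <- array(NA_real_, c(Tn, H, W))
    n_px <- H * W
    sos_jit <- stats::rnorm(n_px, 0, pb$sos_sd)
    eos_jit <- stats::rnorm(n_px, 0, pb$eos_sd)
    amp_fac <- pmax(0.5, stats::rnorm(n_px, 1, pb$amp_frac_sd))
    base_jit <- stats::rnorm(n_px, 0, pb$base_sd)

    px_row <- as.integer(rowi); px_col <- as.integer(coli)
    cls_idx <- labels[cbind(px_row, px_col)]
    p_base <- pmax(0, vapply(config$classes, `[[`, numeric(1), "base")[cls_idx] + base_jit)
    p_amp <- vapply(config$classes, `[[`, numeric(1), "amplitude")[cls_idx] * amp_fac
    p_sos <- vapply(config$classes, `[[`, numeric(1), "sos")[cls_idx] + sos_jit
    p_eos <- vapply(config$classes, `[[`, numeric(1), "eos")[cls_idx] + eos_jit
    p_gr <- vapply(config$classes, `[[`, numeric(1), "growth_rate")[cls_idx]
    p_sr <- vapply(config$classes, `[[`, numeric(1), "senescence_rate")[cls_idx]
    for (idx in seq_len(n_px)) {
      p <- crop_curve_params(base = p_base[idx], amplitude = p_amp[idx],
                             sos = p_sos[idx], eos = p_eos[idx],
                             growth_rate = p_gr[idx], senescence_rate = p_sr[idx])
      clean[, px_row[idx], px_col[idx]] <- double_logistic(times, p, year_offsets = years)
    }
    params <- data.frame(row = px_row, col = px_col, class = cls_names[cls_idx],
                         base = p_base, amplitude = p_amp, sos = p_sos,
                         eos = p_eos, growth_rate = p_gr, senescence_rate = p_sr)
    phenology <- do.call(rbind, lapply(seq_along(years), function(s)
      data.frame(row = px_row, col = px_col, class = cls_names[cls_idx],
                 season = s, sos = p_sos + years[s], eos = p_eos + years[s],
                 amplitude = p_amp, base = p_base)))
    phenology <- phenology[order(phenology$row, phenology$col, phenology$season), ]

    data <- clean
    if (config$noise_sd > 0)
      data <- data + array(stats::rnorm(length(data), 0, config$noise_sd), dim(data))

    valid <- array(TRUE, c(Tn, H, W))
    if (config$cloud_prob > 0) {
      rmin <- max(2, 0.08 * min(H, W)); rmax <- max(rmin + 1, 0.25 * min(H, W))
      for (k in seq_len(Tn))
        valid[k, , ] <- !cloud_mask_one(H, W, config$cloud_prob, rmin, rmax)
    }
    data[!valid] <- NA_real_

    stack <- raster_stack(data, dates = epoch + times, valid_mask = valid,
                          epoch = epoch,
                          geo = list(crs = "synthetic", transform = c(0, 1, 0, 0, 0, -1)))
    cmap <- crop_map(labels, legend = stats::setNames(cls_names, seq_along(cls_names)),
                     parcel_ids = parcel_ids)
    list(stack = stack, crop_map = cmap,
         truth = list(clean = clean, phenology = phenology, params = params))
  })
}

#' Draw a time series from a zero-mean GP with SE covariance
#'
#' Exact draw of the latent function `f ~ N(0, K)` at the given times plus
#' i.i.d. observation noise `N(0, sigma_n^2)` — the generative model the
#' training code assumes, used to test hyperparameter recovery.
#'
#' @param theta A [hyperparams()].
#' @param times Increasing numeric times (days).
#' @param seed Integer seed.
#' @param epoch Epoch date.
#' @return A [time_series()].
#' @export
generate_gp_series <- function(theta, times, seed = 1L,
                               epoch = as.Date("2016-01-01")) {
  stopifnot(inherits(theta, "gpr_theta"))
  times <- as.numeric(times)
  lin <- theta_linear(theta)
  withr::with_seed(as.integer(seed), {
    z <- stats::rnorm(length(times))
    f <- if (lin[["sigma_f2"]] <= 1e-300) {
      numeric(length(times))
    } else {
      K <- se_kernel(times, times, theta) +
        diag(1e-10 * lin[["sigma_f2"]], length(times))
      fac <- chol_with_jitter(K)
      as.numeric(crossprod(fac$R, z))
    }
    y <- f + stats::rnorm(length(times), 0, sqrt(lin[["sigma_n2"]]))
    time_series(times, y, epoch = epoch)
  })
}
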