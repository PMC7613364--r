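# Independent oracles and fixtures used across the suite.
# The oracles deliberately use explicit dense linear algebra (solve, det)
# and hand-written loops, never the package's factorized code paths.

# dense GP posterior + log marginal likelihood, explicit inverse
dense_gp_oracle <- function(t, y, t_star, log_inv_l, log_sf, log_sn) {
  l <- exp(-log_inv_l); sf2 <- exp(2 * log_sf); sn2 <- exp(2 * log_sn)
  kern <- function(a, b) sf2 * exp(-outer(a, b, "-")^2 / (2 * l^2))
  C <- kern(t, t) + diag(sn2, length(t))
  Ci <- solve(C)
  Ks <- kern(t_star, t)
  list(mean = as.numeric(Ks %*% Ci %*% y),
       var = sf2 + sn2 - diag(Ks %*% Ci %*% t(Ks)),
       lml = as.numeric(-0.5 * t(y) %*% Ci %*% y -
                          0.5 * determinant(C)$modulus - length(t) / 2 * log(2 * pi)),
       alpha = as.numeric(Ci %*% y))
}

# central finite differences of the log marginal likelihood
fd_gradient <- function(ts, theta, h = 1e-5) {
  v <- theta_vector(theta)
  vapply(1:3, function(j) {
    vp <- v; vm <- v
    vp[j] <- v[j] + h; vm[j] <- v[j] - h
    (log_marginal_likelihood(ts, theta_from_vector(vp)) -
       log_marginal_likelihood(ts, theta_from_vector(vm))) / (2 * h)
  }, numeric(1))
}

# symmetric triangle series: 0 at day 50, peak `peak` at day 100, 0 at day
# 150, on a daily grid over [0, 200], optionally lifted by `lift`
triangle_series <- function(peak = 5, lift = 0) {
  t <- 0:200
  x <- pmax(0, peak - abs(t - 100) * peak / 50) + lift
  list(times = as.numeric(t), mean = x, epoch = as.Date("2016-01-01"))
}

# minimal recon_result wrapper around a clean T x H x W cube
make_recon <- function(mean_stack, grid, flags = NULL,
                       epoch = as.Date("2016-01-01")) {
  d <- dim(mean_stack)
  if (is.null(flags)) flags <- matrix("ok", d[2], d[3])
  structure(list(mean_stack = mean_stack,
                 sd_stack = array(0, d), grid = grid,
                 grid_dates = epoch + grid, flags = flags,
                 theta_mode = "fixed",
                 ops = list(optimizations = 0L, factorizations = 0L),
                 epoch = epoch, geo = list(), trained = NULL),
            class = "recon_result")
}

# small cloudy multi-crop scene shared by gap-filling tests
small_scene <- function(seed = 11, H = 20, W = 20) {
  generate_scene(scene_config(height = H, width = W, parcel_px = 5,
                              seed = seed))
}
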