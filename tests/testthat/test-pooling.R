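test_that("parcel sampling honours supply, size filters and seeding", {
  # 3 classes x 200 parcels of 60 px each (6 x 10 blocks on a 60 x 600 grid)
  H <- 60; W <- 600
  block_r <- (matrix(rep(1:H, W), H, W) - 1) %/% 6
  block_c <- (matrix(rep(1:W, each = H), H, W) - 1) %/% 10
  pid <- block_r * 60 + block_c + 1
  labels <- ((pid - 1) %% 3) + 1
  map <- crop_map(labels, legend = c("1" = "a", "2" = "b", "3" = "c"),
                  parcel_ids = pid)
  sel <- suppressWarnings(sample_parcels(map, n_parcels = 100,
                                         min_pixels = 50, seed = 7))
  expect_named(sel, c("a", "b", "c"))
  for (cl in names(sel)) {
    expect_equal(length(unique(sel[[cl]]$parcel)), 100)
    expect_equal(nrow(sel[[cl]]), 100 * 60)
  }
  # deterministic given seed
  sel2 <- suppressWarnings(sample_parcels(map, 100, 50, seed = 7))
  expect_identical(sel, sel2)
  expect_false(identical(
    sel$a$parcel,
    suppressWarnings(sample_parcels(map, 100, 50, seed = 8))$a$parcel))

  # all parcels too small -> empty sets with warnings
  tiny <- crop_map(matrix(1L, 5, 2), legend = c("1" = "a"),
                   parcel_ids = matrix(1L, 5, 2))
  expect_warning(out <- sample_parcels(tiny, 10, 50, seed = 1),
                 "no parcels")
  expect_equal(nrow(out$a), 0)
})

test_that("connected components stand in for missing parcel ids", {
  # one class as two disjoint 3x3 blobs, another filling the rest
  labels <- matrix(2L, 10, 10)
  labels[1:3, 1:3] <- 1L
  labels[7:9, 7:9] <- 1L
  map <- crop_map(labels, legend = c("1" = "spots", "2" = "bg"))
  out <- suppressWarnings(sample_parcels(map, n_parcels = 5, min_pixels = 9,
                                         seed = 3))
  expect_equal(length(unique(out$spots$parcel)), 2)
  expect_equal(nrow(out$spots), 18)
})

test_that("hyperparameter averaging is the arithmetic log-space mean", {
  pp <- data.frame(row = 1:4, col = 1L, class = c("a", "a", "b", "b"),
                   log_inv_l = c(-2, -1, -4, -3),
                   log_sigma_f = c(0, 1, -1, 0),
                   log_sigma_n = c(-2, -2, -1, -3),
                   lml = 0, ok = TRUE)
  ts <- average_hyperparameters(pp)
  expect_equal(ts$per_crop$a$log_inv_l, -1.5)
  expect_equal(ts$per_crop$b$log_inv_l, -3.5)
  expect_equal(ts$global$log_inv_l, -2.5)
  # recomputing any group mean from its members reproduces it exactly
  for (cl in c("a", "b")) {
    g <- pp[pp$class == cl, ]
    expect_identical(ts$per_crop[[cl]]$log_sigma_f, mean(g$log_sigma_f))
  }
  # single-pixel group: mean is the pixel itself
  one <- average_hyperparameters(pp[1, ])
  expect_identical(theta_vector(one$per_crop$a),
                   c(log_inv_l = -2, log_sigma_f = 0, log_sigma_n = -2))
  # failed pixels are excluded, empty groups dropped with a warning
  pp$ok[3:4] <- FALSE
  expect_warning(ts2 <- average_hyperparameters(pp), "omitted")
  expect_null(ts2$per_crop$b)
  expect_equal(ts2$global$log_inv_l, -1.5)
})

test_that("a pixel-weighted global mean differs from the mean of crop means", {
  # unbalanced classes: global (per-pixel) average is pulled to the big class
  pp <- data.frame(row = 1:5, col = 1L,
                   class = c("big", "big", "big", "big", "small"),
                   log_inv_l = c(-4, -4, -4, -4, -2),
                   log_sigma_f = 0, log_sigma_n = -2, lml = 0, ok = TRUE)
  ts <- average_hyperparameters(pp)
  expect_equal(ts$global$log_inv_l, -3.6)
  crop_mean <- mean(c(ts$per_crop$big$log_inv_l, ts$per_crop$small$log_inv_l))
  expect_equal(crop_mean, -3.0)
  expect_false(isTRUE(all.equal(ts$global$log_inv_l, crop_mean)))
})

test_that("shipped crop presets document the same weighting distinction", {
  ps <- theta_presets()
  expect_length(ps$per_crop, 9)
  unweighted <- mean(vapply(ps$per_crop, `[[`, numeric(1), "log_inv_l"))
  expect_equal(unweighted, -3.6426, tolerance = 1e-4)
  expect_equal(ps$global$log_inv_l, -3.6430, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unweighted, ps$global$log_inv_l,
                                tolerance = 1e-6)))
})

test_that("per-pixel training recovers a shared theta across pixels", {
  th0 <- hyperparams(-3.0, -0.4, -1.8)
  tms <- seq(0, 1000, by = 8)
  Tn <- length(tms)
  data <- array(NA_real_, c(Tn, 2, 3))
  for (i in 1:6)
    data[, ((i - 1) %% 2) + 1, ((i - 1) %/% 2) + 1] <-
      valid_values(generate_gp_series(th0, tms, seed = 40 + i))
  stack <- raster_stack(data, as.Date("2016-01-01") + tms)
  pts <- expand.grid(row = 1:2, col = 1:3)
  pts$class <- "x"
  out <- train_per_pixel(stack, pts, seed = 2, n_restarts = 3)
  expect_true(all(out$ok))
  expect_true(all(abs(out$log_inv_l - th0$log_inv_l) < 1))
  # determinism: duplicated pixel at the same seed gives identical theta
  again <- train_per_pixel(stack, pts[1, ], seed = 2, n_restarts = 3)
  expect_identical(again$log_inv_l, out$log_inv_l[1])
  # fully masked pixel is recorded as failed, not fatal
  data2 <- data; data2[, 1, 1] <- NA
  stack2 <- raster_stack(data2, as.Date("2016-01-01") + tms)
  out2 <- suppressWarnings(train_per_pixel(stack2, pts[1, ], seed = 2,
                                           n_restarts = 2))
  expect_false(out2$ok[1])
})
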