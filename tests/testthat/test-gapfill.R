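test_that("pixel reconstruction interpolates, reverts and denoises", {
  th <- hyperparams(log(1 / 25), log(1.2), -20)
  t <- seq(0, 200, by = 10); y <- sin(t / 30)
  ts <- time_series(t, y)
  # noiseless GP on the training grid reproduces the observations
  p <- reconstruct_pixel(ts, th, t)
  expect_equal(p$mean, y, tolerance = 1e-8)
  expect_identical(p$flag, "ok")
  # deep in a gap the prediction reverts to the prior
  lin <- theta_linear(th)
  far <- reconstruct_pixel(ts, th, 5000)
  expect_equal(far$mean, 0, tolerance = 1e-6)
  expect_equal(far$sd, sqrt(lin[["sigma_f2"]] + lin[["sigma_n2"]]),
               tolerance = 1e-6)
  # too few valid points -> flagged, not an error
  short <- reconstruct_pixel(time_series(c(0, 10), c(1, 2)), th, t)
  expect_identical(short$flag, "insufficient_data")
  expect_true(all(is.na(short$mean)))

  # denoising: reconstruction closer to the clean curve than the observations
  pcrv <- crop_curve_params(0.3, 3, 60, 180)
  tt <- seq(0, 365, by = 5)
  clean <- double_logistic(tt, pcrv)
  noisy <- clean + withr::with_seed(77, rnorm(length(tt), 0, 0.25))
  tsn <- time_series(tt, noisy)
  tr <- train_hyperparameters(tsn, n_restarts = 3, seed = 4)
  rec <- reconstruct_pixel(tsn, tr$theta, tt)
  expect_lt(rmse(rec$mean, clean), rmse(noisy, clean))
})

test_that("stack reconstruction equals the per-pixel path exactly", {
  th <- theta_presets()$global
  # 2x2 fully observed stack: every pixel equals reconstruct_pixel
  tms <- seq(0, 400, by = 10)
  data <- array(rnorm(length(tms) * 4, 1, 0.3), c(length(tms), 2, 2))
  stack <- raster_stack(data, as.Date("2016-01-01") + tms)
  rs <- reconstruct_stack(stack, th, mode = "fixed", step = 20)
  for (r in 1:2) for (c in 1:2) {
    pp <- reconstruct_pixel(pixel_series(stack, r, c), th, rs$grid)
    expect_equal(rs$mean_stack[, r, c], pp$mean, tolerance = 1e-12)
    expect_equal(rs$sd_stack[, r, c], pp$sd, tolerance = 1e-12)
  }

  # shared-factorization fast path vs naive loop on a cloudy 20x20 scene
  scene <- small_scene(seed = 31)
  fast <- reconstruct_stack(scene$stack, th, mode = "fixed", step = 10)
  naive <- reconstruct_stack(scene$stack, th, mode = "fixed", step = 10,
                             share = FALSE)
  expect_lt(max(abs(fast$mean_stack - naive$mean_stack), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(fast$sd_stack - naive$sd_stack), na.rm = TRUE), 1e-10)
  expect_identical(fast$ops$optimizations, 0L)
})

test_that("per-crop mode uses class thetas with global fallback", {
  scene <- small_scene(seed = 13, H = 10, W = 10)
  ps <- theta_presets()
  # drop one class present in the scene from the per-crop table
  present <- unique(as.vector(scene$crop_map$labels))
  dropped <- class_name(scene$crop_map, present[1])
  ts2 <- theta_set(per_crop = ps$per_crop[setdiff(names(ps$per_crop), dropped)],
                   global = ps$global)
  rec <- reconstruct_stack(scene$stack, ts2, mode = "per_crop",
                           crop_map = scene$crop_map, step = 20)
  in_dropped <- scene$crop_map$labels == present[1]
  expect_true(all(rec$flags[in_dropped] %in%
                    c("fallback_global", "insufficient_data")))
  # fallback pixels match a pure-global reconstruction
  glob <- reconstruct_stack(scene$stack, ps, mode = "global", step = 20)
  i <- which(rec$flags == "fallback_global")[1]
  r <- ((i - 1) %% 10) + 1; c <- ((i - 1) %/% 10) + 1
  expect_equal(rec$mean_stack[, r, c], glob$mean_stack[, r, c],
               tolerance = 1e-12)
  # without fallback those pixels are flagged unusable
  rec2 <- reconstruct_stack(scene$stack, theta_set(per_crop = ts2$per_crop),
                            mode = "per_crop", crop_map = scene$crop_map,
                            step = 20, fallback_global = FALSE)
  expect_true(all(rec2$flags[in_dropped] == "no_theta"))
  idx <- which(in_dropped, arr.ind = TRUE)
  for (k in seq_len(nrow(idx)))
    expect_true(all(is.na(rec2$mean_stack[, idx[k, 1], idx[k, 2]])))
  # per-crop without a crop map is a config error
  expect_error(reconstruct_stack(scene$stack, ps, mode = "per_crop"),
               class = "phenofill_config")
})

test_that("training-cost model counts optimizations and factorizations", {
  tms <- seq(0, 200, by = 10)
  Tn <- length(tms)
  data <- array(1 + rnorm(Tn * 100, 0, 0.1), c(Tn, 10, 10))
  stack <- raster_stack(data, as.Date("2016-01-01") + tms)
  # identical masks: one factorization serves the whole scene
  fixed <- count_training_ops(stack, "fixed")
  expect_equal(fixed$optimizations, 0L)
  expect_equal(fixed$factorizations, 1L)
  # per-pixel: one optimization per trainable pixel
  pp <- count_training_ops(stack, "per_pixel")
  expect_equal(pp$optimizations, 100L)
  # k distinct valid patterns -> k factorizations
  mask <- array(TRUE, dim(data))
  mask[1, , 1:3] <- FALSE   # pattern 2 in columns 1..3
  mask[2, , 4] <- FALSE     # pattern 3 in column 4
  data2 <- data; data2[!mask] <- NA
  stack2 <- raster_stack(data2, as.Date("2016-01-01") + tms, valid_mask = mask)
  expect_equal(count_training_ops(stack2, "fixed")$factorizations, 3L)
  # the executed fast path agrees with the predicted counts
  rec <- reconstruct_stack(stack2, theta_presets()$global, mode = "fixed",
                           step = 50)
  expect_equal(rec$ops$factorizations, 3L)
  expect_equal(rec$ops$optimizations, 0L)
})
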