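test_that("season detection resolves peaks, valleys and degenerate series", {
  # single symmetric triangle
  tri <- triangle_series(peak = 5)
  segs <- detect_seasons(tri)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$peak_time, 100)
  expect_equal(segs$peak_value, 5)
  expect_equal(segs$base_level, 0)

  # two equal peaks share the valley minimum as right/left flank
  t <- 0:200
  x <- pmax(0, 5 - abs(t - 50) / 10) + pmax(0, 5 - abs(t - 150) / 10)
  two <- detect_seasons(list(times = t, mean = x))
  expect_equal(nrow(two), 2)
  expect_equal(two$peak_time, c(50, 150))
  expect_identical(two$right_idx[1], two$left_idx[2])
  expect_equal(two$right_time[1], 100)

  # monotone ramp and flat series yield nothing
  expect_equal(nrow(detect_seasons(list(times = t, mean = t / 10))), 0)
  expect_equal(nrow(detect_seasons(list(times = t, mean = rep(2, 201)))), 0)

  # low-prominence wiggles are ignored
  wig <- 5 + 0.01 * sin(t / 5) + pmax(0, 5 - abs(t - 100) / 10)
  one <- detect_seasons(list(times = t, mean = wig), min_prominence = 0.1)
  expect_equal(nrow(one), 1)

  # short blips are dropped by the minimum season length
  blip <- pmax(0, 5 - abs(t - 100)) # 10-day-wide triangle
  expect_equal(nrow(detect_seasons(list(times = t, mean = blip),
                                   min_season_length = 30)), 0)
})

test_that("triangle season metrics are exact, including the lifted variant", {
  tri <- triangle_series(peak = 5)
  seg <- detect_seasons(tri)
  m <- season_metrics(seg[1, ], tri, threshold_frac = 0.20)
  expect_equal(m$sos, 60); expect_equal(m$eos, 140)
  expect_equal(m$los, 80); expect_equal(m$dom, 100)
  expect_equal(m$amplitude, 5); expect_equal(m$max_value, 5)
  expect_equal(m$blue_area, 240, tolerance = 1e-9)
  expect_equal(m$green_area, 240, tolerance = 1e-9)

  # lifting by +1: amplitude and crossings unchanged, blue gains 1 * LOS
  tri2 <- triangle_series(peak = 5, lift = 1)
  seg2 <- detect_seasons(tri2)
  m2 <- season_metrics(seg2[1, ], tri2, threshold_frac = 0.20)
  expect_equal(m2$amplitude, 5)
  expect_equal(m2$sos, 60); expect_equal(m2$eos, 140)
  expect_equal(m2$green_area, 240, tolerance = 1e-9)
  expect_equal(m2$blue_area, 240 + 1 * 80, tolerance = 1e-9)

  # threshold 0 degenerates to the flanking minima
  m0 <- season_metrics(seg[1, ], tri, threshold_frac = 0)
  expect_equal(m0$sos, seg$left_time[1])
  expect_equal(m0$eos, seg$right_time[1])
})

test_that("metric invariants hold on every emitted record", {
  scene <- small_scene(seed = 19, H = 8, W = 8)
  rec <- reconstruct_stack(scene$stack, theta_presets()$global,
                           mode = "fixed", step = 10)
  ph <- phenology_maps(rec, by = "year")
  ok <- ph$records[ph$records$flag == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_equal(ok$los, ok$eos - ok$sos, tolerance = 1e-12)
  expect_true(all(ok$sos < ok$dom & ok$dom < ok$eos))
  expect_true(all(is.finite(ok$amplitude) & ok$amplitude > 0))
})

test_that("daily-grid crossings of clean double-logistic curves are sharp", {
  for (nm in c("wheat", "corn", "alfalfa")) {
    p <- default_crop_library()[[nm]]
    t <- 0:365
    ser <- list(times = t, mean = double_logistic(t, p),
                epoch = as.Date("2016-01-01"))
    ph <- extract_phenology(ser, threshold_frac = 0.20)
    expect_equal(nrow(ph), 1)
    cr <- curve_crossings(p, 0.20)
    expect_lt(abs(ph$sos - cr["rise"]), 1)
    expect_lt(abs(ph$eos - cr["fall"]), 1)
  }
})

test_that("phenology maps propagate spatial structure and nodata", {
  # uniform scene: constant maps equal to the single-pixel metrics
  p <- default_crop_library()$wheat
  grid <- seq(0, 365, by = 5)
  curve <- double_logistic(grid, p)
  cube <- array(rep(curve, 3 * 3), c(length(grid), 3, 3))
  rec <- make_recon(cube, grid)
  ph <- phenology_maps(rec)
  expect_equal(length(ph$slots), 1)
  sos_map <- ph$maps$sos[, , 1]
  expect_true(all(abs(sos_map - sos_map[1, 1]) < 1e-9))
  single <- extract_phenology(list(times = grid, mean = curve,
                                   epoch = rec$epoch))
  expect_equal(unname(sos_map[1, 1]), single$sos)

  # two classes with offset start: the SOS map is bimodal at the truth values
  p2 <- default_crop_library()$corn
  cube2 <- cube
  cube2[, , 3] <- double_logistic(grid, p2)
  ph2 <- phenology_maps(make_recon(cube2, grid))
  sos2 <- ph2$maps$sos[, , 1]
  expect_true(all(abs(sos2[, 1:2] - curve_crossings(p, 0.2)["rise"]) <= 5))
  expect_true(all(abs(sos2[, 3] - curve_crossings(p2, 0.2)["rise"]) <= 5))

  # flagged pixel -> nodata in every metric layer
  flags <- matrix("ok", 3, 3); flags[2, 2] <- "insufficient_data"
  cube3 <- cube; cube3[, 2, 2] <- NA
  ph3 <- phenology_maps(make_recon(cube3, grid, flags = flags))
  for (m in names(ph3$maps)) expect_true(all(is.na(ph3$maps[[m]][2, 2, ])))
})
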