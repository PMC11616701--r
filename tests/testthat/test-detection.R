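# Detection pipeline: background, segmentation, measurement, filtering.

test_that("background of constant frames is their per-pixel mean", {
  mats <- list(matrix(100L, 8, 8), matrix(102L, 8, 8))
  seq <- frames_in_memory(mats)
  for (method in c("median", "mean")) {
    bg <- estimate_background(seq, detection_config(background_method = method))
    expect_true(all(bg$background == 101))
  }
})

test_that("noise SD is recovered from i.i.d. Gaussian noise", {
  set.seed(4)
  mats <- lapply(1:60, function(i) {
    matrix(as.integer(round(200 + rnorm(40 * 60, 0, 2))), 40, 60)
  })
  bg <- estimate_background(frames_in_memory(mats), detection_config())
  expect_lt(abs(bg$noise_sd - 2), 0.3)
  bg2 <- estimate_background(frames_in_memory(mats), detection_config(),
                             noise_sd_image = TRUE)
  expect_lt(abs(mean(bg2$noise_sd_image) - 2), 0.3)
})

test_that("background stays within 1 count of truth with transiting cells", {
  spec <- calibrated_populations()$pbmc
  # duty 0.25 keeps per-pixel occupancy at or below ~5 %
  sim <- simulate_cells(spec, 200, imaging_config(), seed = 6, duty = 0.25)
  bg <- estimate_background(sim$frames, detection_config())
  # systematic bias vs the cell-free level; per-pixel sampling noise of a
  # finite-frame median is ~2-3 counts and averages out
  expect_lt(abs(mean(bg$background - 200)), 1)
  # bias specifically on the cell-traffic stripes around channel centrelines
  cols <- unlist(lapply(imaging_config()$channel_centers_px,
                        function(cc) round(cc + (-10:10)) + 1))
  expect_lt(abs(mean(bg$background[, cols] - 200)), 1)
})

test_that("a single-frame sequence warns and returns that frame", {
  mats <- list(matrix(7L, 4, 4))
  expect_warning(bg <- estimate_background(frames_in_memory(mats)),
                 "single-frame")
  expect_true(all(bg$background == 7))
})

test_that("cell-free noise frames yield no candidates at the 6-sigma threshold", {
  cfg <- quick_config()
  set.seed(8)
  for (i in 1:5) {
    fr <- render_frame(NULL, cfg, seed = i)
    ct <- segment_frame(fr, matrix(cfg$background_level, 80, 256),
                        detection_config(), noise_sd = sqrt(204))
    expect_length(ct, 0L)
  }
})

test_that("a rendered disk is segmented with area within 2% of pi r^2", {
  cfg <- quick_config(read_noise_sd = 0, shot_noise = FALSE)
  cells <- data.frame(p = 0, base_radius_um = 5, x_um = 64, y_um = 20,
                      velocity = 0, intensity_contrast = 0.85)
  fr <- render_frame(cells, cfg, noise = FALSE)
  ct <- segment_frame(fr, matrix(cfg$background_level, 80, 256),
                      detection_config(), noise_sd = sqrt(204))
  expect_length(ct, 1L)
  expect_lt(abs(polygon_area(ct[[1]]) - pi * 100) / (pi * 100), 0.02)
})

test_that("saturated frames are rejected with a reason", {
  fr <- matrix(255L, 80, 256)
  ct <- segment_frame(fr, matrix(200, 80, 256), detection_config(), 14)
  expect_length(ct, 0L)
  expect_identical(attr(ct, "rejected"), "saturated")
})

test_that("cells in different channels give distinct channel assignments", {
  cfg <- quick_config()  # channels at x = 64, 192 px
  cells <- data.frame(p = c(0.5, 0.5), base_radius_um = 4,
                      x_um = c(32, 96), y_um = 20, velocity = 0.7,
                      intensity_contrast = 0.85)
  fr <- render_frame(cells, cfg, seed = 12)
  ct <- segment_frame(fr, matrix(cfg$background_level, 80, 256),
                      detection_config(), sqrt(204))
  expect_length(ct, 2L)
  recs <- do.call(rbind, lapply(ct, measure_cell, frame = fr,
                                calibration = cfg, frame_index = 1L))
  expect_setequal(recs$channel_id, c(1L, 2L))
})

test_that("measure_cell reproduces closed-form shape descriptors", {
  fr <- matrix(100L, 80, 256)
  cfg <- quick_config()
  # circle: D = 0 (within discretisation tolerance)
  rec <- measure_cell(circle_contour(10, 50, 40), fr, calibration = cfg)
  expect_lt(abs(rec$deformability), 0.005)
  expect_equal(rec$area_um2, pi * 100 * 0.25, tolerance = 0.01)
  expect_lt(abs(rec$aspect_ratio - 1), 0.05)
  expect_lt(abs(rec$area_ratio - 1), 0.005)
  # square: D = 1 - sqrt(pi)/2
  rec <- measure_cell(square_contour(20, 100, 30), fr, calibration = cfg)
  expect_equal(rec$deformability, 1 - sqrt(pi) / 2, tolerance = 1e-3)
  # 2:1 ellipse: aspect ratio 2.0 +/- 0.05
  rec <- measure_cell(ellipse_contour(20, 10, 128, 40), fr, calibration = cfg)
  expect_lt(abs(rec$aspect_ratio - 2), 0.05)
  expect_equal(rec$area_um2, pi * 20 * 10 * 0.25, tolerance = 0.02)
})

test_that("brightness is the mean original intensity inside the contour", {
  fr <- matrix(200L, 80, 256)
  fr[30:50, 40:60] <- 90L
  rec <- measure_cell(square_contour(20, 40, 30), fr, calibration = quick_config())
  expect_equal(rec$brightness, 90, tolerance = 1)
})

test_that("degenerate contours are rejected records", {
  fr <- matrix(100L, 20, 20)
  bad <- cbind(x = rep(5, 10), y = rep(5, 10))
  rec <- measure_cell(bad, fr, calibration = quick_config())
  expect_false(rec$accepted)
  expect_identical(rec$reject_reason, "degenerate")
})

test_that("presence filter rejects by area, concavity, and border", {
  cfg <- quick_config()
  dc <- detection_config()
  fr <- matrix(100L, 80, 256)
  # convex bullet-like disk: accepted
  rec <- presence_filter(measure_cell(circle_contour(8, 64, 40), fr,
                                      calibration = cfg), dc, cfg)
  expect_true(rec$accepted)
  # crescent: hull/area ~ 1.4 -> rejected as concave debris
  rec <- presence_filter(measure_cell(crescent_contour(cx = 64, cy = 40), fr,
                                      calibration = cfg), dc, cfg)
  expect_false(rec$accepted)
  expect_match(rec$reject_reason, "area_ratio")
  expect_gt(rec$area_ratio, 1.25)
  # contour 2 px from the ROI edge -> border
  rec <- presence_filter(measure_cell(circle_contour(8, 10, 40), fr,
                                      calibration = cfg), dc, cfg)
  expect_false(rec$accepted)
  expect_match(rec$reject_reason, "border")
  # too small / too large
  rec <- presence_filter(measure_cell(circle_contour(3, 64, 40), fr,
                                      calibration = cfg), dc, cfg)
  expect_match(rec$reject_reason, "area_min")
  rec <- presence_filter(measure_cell(circle_contour(35, 128, 40), fr,
                                      calibration = cfg), dc, cfg)
  expect_match(rec$reject_reason, "area_max")
})

test_that("clean synthetic streams are recovered completely and idempotently", {
  spec <- calibrated_populations()$pbmc
  sim <- simulate_cells(spec, 300, imaging_config(), seed = 10)
  res1 <- process_sequence(sim$frames)
  expect_equal(sum(res1$accepted), nrow(sim$manifest))
  expect_equal(nrow(res1), nrow(sim$manifest))
  counters <- attr(res1, "counters")
  expect_equal(unname(counters["candidates"]), 300)
  # idempotence
  res2 <- process_sequence(sim$frames)
  attr(res1, "counters") <- attr(res2, "counters") <- NULL
  attr(res1, "reject_reasons") <- attr(res2, "reject_reasons") <- NULL
  expect_identical(res1, res2)
})

test_that("an empty sequence yields an empty table", {
  seq <- frame_sequence(0, function(i) stop("no frames"))
  res <- process_sequence(seq, calibration = quick_config())
  expect_s3_class(res, "results_table")
  expect_equal(nrow(res), 0L)
})

test_that("velocity is estimated from frame-to-frame displacement", {
  cfg <- imaging_config(frame_rate_hz = 10000)  # 0.2 m/s -> 40 px/frame
  cells1 <- data.frame(p = 0.5, base_radius_um = 4, x_um = 51.2 / 2 * 0.5 * 2,
                       y_um = 10, velocity = 0.2, intensity_contrast = 0.85)
  cells1$x_um <- cfg$channel_centers_px[3] * cfg$pixel_size_um
  cells2 <- cells1; cells2$y_um <- 10 + 20  # 40 px * 0.5 um
  frames <- frames_in_memory(list(render_frame(cells1, cfg, seed = 1),
                                  render_frame(cells2, cfg, seed = 2),
                                  render_frame(NULL, cfg, seed = 3)),
                             config = cfg)
  res <- process_sequence(frames, detection_config(threshold = 85),
                          calibration = cfg)
  res <- estimate_velocity(res, cfg)
  v <- res$velocity_mps[res$frame_index == 1]
  expect_length(v, 1L)
  # within one pixel equivalent: 0.5 um x 10 kHz = 0.005 m/s
  expect_lt(abs(v - 0.2), 0.005)
  # second appearance has no successor -> no estimate
  expect_true(is.na(res$velocity_mps[res$frame_index == 2]))
})

test_that("zero displacement yields zero velocity", {
  cfg <- imaging_config(frame_rate_hz = 1000)
  cells <- data.frame(p = 0.5, base_radius_um = 4,
                      x_um = cfg$channel_centers_px[5] * cfg$pixel_size_um,
                      y_um = 20, velocity = 0, intensity_contrast = 0.85)
  frames <- frames_in_memory(list(render_frame(cells, cfg, seed = 4),
                                  render_frame(cells, cfg, seed = 5)),
                             config = cfg)
  # the cell sits still, so it would dominate a 2-frame background estimate;
  # supply the known cell-free background instead
  bg <- list(background = matrix(200, 80, 1024), noise_sd = 14.2)
  res <- estimate_velocity(process_sequence(frames, detection_config(threshold = 85),
                                            calibration = cfg, background = bg),
                           cfg)
  expect_equal(nrow(res), 2L)
  expect_lt(abs(res$velocity_mps[1]), 1e-3)
})
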