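# Frame rendering: noise model, motion blur, rasterisation fidelity.

test_that("an empty scene is a pure noise frame at the background level", {
  cfg <- quick_config()
  fr <- render_frame(NULL, cfg, seed = 1)
  n <- length(fr)
  se <- sqrt(cfg$background_level + cfg$read_noise_sd^2) / sqrt(n)
  expect_lt(abs(mean(fr) - cfg$background_level), 3 * se + 0.05)
  expect_true(is.integer(fr))
  expect_equal(dim(fr), c(80L, 256L))
})

test_that("motion-blur length follows velocity x exposure / pixel size", {
  cfg <- imaging_config(exposure_s = 2e-6, pixel_size_um = 0.5)
  expect_equal(motion_blur_px(0.7, cfg), 2.8)
  expect_equal(motion_blur_px(0, cfg), 0)
})

test_that("a blur length reaching the flow-axis ROI extent is a config error", {
  cfg <- quick_config()
  cells <- data.frame(p = 0, base_radius_um = 4, x_um = 64, y_um = 20,
                      velocity = 20, intensity_contrast = 0.85)  # 80 px blur
  expect_error(render_frame(cells, cfg, seed = 1), "blur")
})

test_that("noise-free, PSF-free rendering matches the raster oracle within 2%", {
  cfg <- quick_config(psf_sigma_px = 0, read_noise_sd = 0, shot_noise = FALSE)
  r_um <- 7  # 14 px radius
  cells <- data.frame(p = 0, base_radius_um = r_um, x_um = 64, y_um = 20,
                      velocity = 0, intensity_contrast = 0.85)
  fr <- render_frame(cells, cfg, noise = FALSE)
  dark <- sum(fr < cfg$background_level * (1 - 0.85 / 2))
  # raster oracle: pixel centres inside the circle
  px <- cfg$pixel_size_um
  gx <- (0:255) * px; gy <- (0:79) * px
  inside <- outer(gy, gx, function(y, x) (x - 64)^2 + (y - 20)^2 <= r_um^2)
  expect_lt(abs(dark - sum(inside)) / sum(inside), 0.02)
})

test_that("rendering is deterministic under a fixed seed", {
  cfg <- quick_config()
  cells <- data.frame(p = 1, base_radius_um = 4, x_um = 64, y_um = 20,
                      velocity = 0.7, intensity_contrast = 0.85)
  f1 <- render_frame(cells, cfg, seed = 99)
  f2 <- render_frame(cells, cfg, seed = 99)
  expect_identical(f1, f2)
})

test_that("simulated streams are byte-identical across runs at a fixed seed", {
  spec <- calibrated_populations()$pbmc
  s1 <- simulate_stream(spec, 1, arrival_rate_per_channel = 20,
                        duration_s = 0.01, config = quick_config(), seed = 5)
  s2 <- simulate_stream(spec, 1, arrival_rate_per_channel = 20,
                        duration_s = 0.01, config = quick_config(), seed = 5)
  expect_identical(as.data.frame(s1$manifest), as.data.frame(s2$manifest))
  for (i in seq_len(n_frames(s1$frames))) {
    expect_identical(get_frame(s1$frames, i), get_frame(s2$frames, i))
  }
})

test_that("Poisson arrivals and spiking mixtures behave as specified", {
  cfg <- imaging_config()
  spec <- calibrated_populations()$pbmc
  # rate 10/s/channel x 1 s x 10 channels -> Poisson(100) total
  totals <- vapply(1:30, function(s) {
    nrow(simulate_stream(spec, 1, arrival_rate_per_channel = 10,
                         duration_s = 1, config = cfg, seed = s)$manifest)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 100), 3 * sqrt(100 / 30))
  # spiked mixture fraction is binomial around the weight
  specs <- list(calibrated_populations()$rbc, calibrated_populations()$bt474)
  sim <- simulate_stream(specs, c(0.999, 0.001), arrival_rate_per_channel = 500,
                         duration_s = 2, config = cfg, seed = 7)
  frac <- mean(sim$manifest$population == "bt474")
  n <- nrow(sim$manifest)
  expect_lt(abs(frac - 0.001), 3 * sqrt(0.001 / n) + 1e-4)
})

test_that("manifest JSON round-trips", {
  spec <- calibrated_populations()$pbmc
  sim <- simulate_cells(spec, 20, quick_config(), seed = 8)
  path <- tempfile(fileext = ".json")
  write_manifest(sim$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$area_true, sim$manifest$area_true, tolerance = 1e-12)
  expect_equal(attr(back, "n_frames"), attr(sim$manifest, "n_frames"))
  expect_equal(attr(back, "seed"), attr(sim$manifest, "seed"))
})
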