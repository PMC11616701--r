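# Imaging configuration and bright-field frame rendering.

#' Imaging configuration
#'
#' Describes the virtual camera and optics: region-of-interest geometry,
#' calibration, frame timing, noise model, and the parallel-channel layout.
#' Defaults follow a 10-channel device imaged at 20x-class magnification:
#' a 1024 x 80 px ROI spanning the channels, 0.5 um/px, 2 us exposure, and a
#' recording rate of 1000 frames/s (10000 also typical). The flow axis is the
#' image y axis; `channel_centers_px` are x positions of the channel
#' centrelines.
#'
#' @param roi_width_px,roi_height_px ROI size in pixels.
#' @param pixel_size_um calibration, micrometres per pixel.
#' @param frame_rate_hz recording rate (1/s).
#' @param exposure_s exposure time (s); with the transit velocity it sets the
#'   motion-blur length `velocity * exposure / pixel_size`.
#' @param bit_depth stored bit depth (8 or 16).
#' @param background_level bright-field background (counts).
#' @param read_noise_sd Gaussian read noise SD (counts); 0 disables it.
#' @param psf_sigma_px Gaussian point-spread sigma (pixels); 0 disables it.
#' @param n_channels number of parallel deformation channels.
#' @param channel_centers_px x centres of the channels (pixels); defaults to
#'   an even layout across the ROI width.
#' @param shot_noise apply Poisson shot noise (`TRUE` by default).
#' @param rim_width_px width of the dark cell rim drawn at the contour (px).
#' @param supersample antialiasing factor for cell rasterisation.
#' @return An `imaging_config` object.
#' @export
imaging_config <- function(roi_width_px = 1024L, roi_height_px = 80L,
                           pixel_size_um = 0.5, frame_rate_hz = 1000,
                           exposure_s = 2e-6, bit_depth = 8L,
                           background_level = 200, read_noise_sd = 2,
                           psf_sigma_px = 0.7, n_channels = 10L,
                           channel_centers_px = NULL, shot_noise = TRUE,
                           rim_width_px = 0.8, supersample = 4L) {
  stopifnot(roi_width_px > 0, roi_height_px > 0, pixel_size_um > 0,
            frame_rate_hz > 0, exposure_s > 0, bit_depth %in% c(8L, 16L),
            background_level > 0, read_noise_sd >= 0, psf_sigma_px >= 0,
            n_channels >= 1)
  if (is.null(channel_centers_px)) {
    pitch <- roi_width_px / n_channels
    channel_centers_px <- pitch * (seq_len(n_channels) - 0.5)
  }
  stopifnot(length(channel_centers_px) == n_channels)
  structure(list(roi_width_px = as.integer(roi_width_px),
                 roi_height_px = as.integer(roi_height_px),
                 pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz,
                 exposure_s = exposure_s,
                 bit_depth = as.integer(bit_depth),
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 psf_sigma_px = psf_sigma_px,
                 n_channels = as.integer(n_channels),
                 channel_centers_px = channel_centers_px,
                 shot_noise = isTRUE(shot_noise),
                 rim_width_px = rim_width_px,
                 supersample = as.integer(supersample)),
            class = "imaging_config")
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf("imaging_config: %d x %d px @ %.2f um/px, %g fps, %g us exposure, %d-bit, %d channels\n",
              x$roi_width_px, x$roi_height_px, x$pixel_size_um,
              x$frame_rate_hz, x$exposure_s * 1e6, x$bit_depth, x$n_channels))
  invisible(x)
}

#' Motion-blur length in pixels
#'
#' @param velocity_mps transit velocity (m/s).
#' @param config an [imaging_config()].
#' @return Blur length `velocity * exposure / pixel_size` in pixels.
#' @export
motion_blur_px <- function(velocity_mps, config) {
  velocity_mps * config$exposure_s * 1e6 / config$pixel_size_um
}

# fractional box kernel of total length L (px), symmetric, sums to 1
.box_kernel <- function(L) {
  if (L <= 1) return(1)
  h <- L / 2
  r <- ceiling(h - 0.5 + 1e-12)
  off <- -r:r
  w <- pmax(pmin(off + 0.5, h) - pmax(off - 0.5, -h), 0)
  w / sum(w)
}

.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# 1-D convolution along rows (y) of a matrix with symmetric kernel, constant pad
.convolve_y <- function(m, k, pad) {
  if (length(k) == 1L) return(m)
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  mp <- rbind(matrix(pad, r, ncol(m)), m, matrix(pad, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  out
}

# rasterise one cell as a transmission (multiplicative) window.
# Returns list(rows, cols, frac) in 1-based matrix indices.
.render_cell_window <- function(p, r0_px, cx_px, cy_px, contrast, blur_px,
                                config) {
  nt <- 1024L
  tg <- seq(0, 2 * pi, length.out = nt + 1L)
  rg <- r0_px * .bullet_radius(tg, p)
  stretch <- 1 + .bullet$stretch * p
  rim_c <- contrast + 0.6 * (1 - contrast)
  ext_u <- max(rg) * stretch
  ext_v <- max(rg)
  pad <- 2 + ceiling(blur_px / 2)
  # pixel index ranges (0-based px coords), clamped to ROI
  x0 <- max(0L, floor(cx_px - ext_v - 2)); x1 <- min(config$roi_width_px - 1L, ceiling(cx_px + ext_v + 2))
  y0 <- max(0L, floor(cy_px - ext_u - pad)); y1 <- min(config$roi_height_px - 1L, ceiling(cy_px + ext_u + pad))
  if (x1 < x0 || y1 < y0) return(NULL)
  ss <- config$supersample
  rim_w <- config$rim_width_px
  # orientation pi/2: local flow axis u = image y, transverse v = image x
  npy <- length(y0:y1); npx <- length(x0:x1)
  u <- rep((y0:y1) - cy_px, times = npx)
  v <- rep((x0:x1) - cx_px, each = npy)
  classify <- function(uu, vv) {
    us <- uu / stretch
    rad <- sqrt(us * us + vv * vv)
    rad - approx(tg, rg, xout = atan2(vv, us) %% (2 * pi))$y
  }
  din <- classify(u, v)  # signed distance proxy at pixel centres
  val <- rep(1, npy * npx)
  val[din <= 0] <- 1 - rim_c
  val[din <= -rim_w] <- 1 - contrast
  # supersample only pixels whose window can straddle a transition
  band <- which(din > -rim_w - 0.9 & din < 0.9)
  if (length(band) && ss > 1) {
    off <- (seq_len(ss) - 0.5) / ss - 0.5
    offg <- expand.grid(dy = off, dx = off)
    nb <- length(band); no <- nrow(offg)
    ub <- rep(u[band], times = no) + rep(offg$dy, each = nb)
    vb <- rep(v[band], times = no) + rep(offg$dx, each = nb)
    dinb <- classify(ub, vb)
    vb2 <- rep(1, nb * no)
    vb2[dinb <= 0] <- 1 - rim_c
    vb2[dinb <= -rim_w] <- 1 - contrast
    val[band] <- rowMeans(matrix(vb2, nb, no))
  }
  frac <- matrix(val, npy, npx)
  # per-cell motion blur along the flow axis
  frac <- .convolve_y(frac, .box_kernel(blur_px), pad = 1)
  list(rows = (y0:y1) + 1L, cols = (x0:x1) + 1L, frac = frac)
}

#' Render one bright-field frame
#'
#' Composites bullet-shaped cells onto a bright background as dark rims with a
#' slightly lighter interior, applies per-cell motion blur along the flow axis
#' (box kernel of length `velocity * exposure / pixel_size`), a global
#' Gaussian point-spread blur, Poisson shot noise and Gaussian read noise, and
#' quantises to the configured bit depth.
#'
#' @param cells data frame of cells to draw; needs columns `p`,
#'   `base_radius_um`, `x_um`, `y_um`, `velocity`, `intensity_contrast`
#'   (as produced by [simulate_stream()]/[simulate_cells()]). May be empty.
#' @param config an [imaging_config()].
#' @param seed optional integer seed for the noise draws.
#' @param noise set `FALSE` to disable all noise regardless of config.
#' @return Integer matrix `roi_height_px x roi_width_px` (rows = y).
#' @export
render_frame <- function(cells, config, seed = NULL, noise = TRUE) {
  H <- config$roi_height_px; W <- config$roi_width_px
  img <- matrix(config$background_level, H, W)
  if (!is.null(cells) && nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      blur <- motion_blur_px(cells$velocity[i], config)
      if (blur >= H) {
        stop(sprintf("motion-blur length %.1f px reaches the ROI extent along the flow axis (%d px); reduce velocity or exposure",
                     blur, H))
      }
      w <- .render_cell_window(cells$p[i],
                               cells$base_radius_um[i] / config$pixel_size_um,
                               cells$x_um[i] / config$pixel_size_um,
                               cells$y_um[i] / config$pixel_size_um,
                               cells$intensity_contrast[i], blur, config)
      if (!is.null(w)) {
        img[w$rows, w$cols] <- img[w$rows, w$cols] * w$frac
      }
    }
  }
  if (config$psf_sigma_px > 0) {
    kg <- .gauss_kernel(config$psf_sigma_px)
    img <- .convolve_y(img, kg, pad = config$background_level)
    img <- t(.convolve_y(t(img), kg, pad = config$background_level))
  }
  maxval <- 2^config$bit_depth - 1
  if (noise) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    v <- as.vector(img)
    if (config$shot_noise) v <- rpois(length(v), lambda = pmax(v, 0))
    if (config$read_noise_sd > 0) v <- v + rnorm(length(v), 0, config$read_noise_sd)
    img <- matrix(v, H, W)
  }
  m <- round(img)
  m[m < 0] <- 0; m[m > maxval] <- maxval
  storage.mode(m) <- "integer"
  m
}
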