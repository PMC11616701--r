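# Assembly of synthetic frame sequences: cell placement, arrival processes,
# and the truth manifest that records every rendered cell exactly once.

# derive a per-frame noise seed from the stream seed (kept below 2^31)
.frame_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

# y-placement band (um) that keeps the whole blurred cell inside the ROI
.safe_band_um <- function(truth, config, margin_px) {
  stretch <- 1 + .bullet$stretch * truth$p
  nose <- stretch * (1 + truth$p * (.bullet$a2 + .bullet$a3)) * truth$base_radius_um
  tail <- stretch * abs(1 + truth$p * (.bullet$a2 - .bullet$a3)) * truth$base_radius_um
  blur_um <- motion_blur_px(truth$velocity, config) / 2 * config$pixel_size_um
  px <- config$pixel_size_um
  lo <- (margin_px + 2) * px + tail + blur_um
  hi <- (config$roi_height_px - 1 - margin_px - 2) * px - nose - blur_um
  cbind(lo = lo, hi = pmax(hi, lo))
}

.finish_manifest <- function(truth, config, seed, specs, weights) {
  truth$centroid_true_x <- truth$x_um
  truth$centroid_true_y <- truth$y_um + .family_at(truth$p, "centroid_u") * truth$base_radius_um
  attr(truth, "config") <- config
  attr(truth, "seed") <- seed
  attr(truth, "specs") <- specs
  attr(truth, "weights") <- weights
  class(truth) <- c("truth_manifest", "synthetic_truth", "data.frame")
  truth
}

# lazy generator-backed sequence over a manifest
.manifest_sequence <- function(manifest, config, seed, noise = TRUE) {
  n_frames <- attr(manifest, "n_frames")
  idx <- split(seq_len(nrow(manifest)), factor(manifest$frame_index,
                                               levels = seq_len(n_frames)))
  frame_sequence(
    n_frames = n_frames,
    get_frame = function(i) {
      render_frame(manifest[idx[[i]], , drop = FALSE], config,
                   seed = .frame_seed(seed, i), noise = noise)
    },
    config = config, source = "synthetic")
}

#' Simulate a fixed number of cells in a clean stream
#'
#' Deterministic round-robin placement over channel/frame slots, jittered
#' around the channel centreline and positioned so no cell touches the ROI
#' border. This is the layout used for calibration/recovery experiments where
#' every rendered cell should yield exactly one accepted record. Slots are
#' filled at a duty cycle chosen so that the per-pixel cell occupancy stays
#' low enough for robust background estimation (large cells sweep a larger
#' fraction of their placement band, so they are spread over more frames).
#'
#' @param spec a [population_spec()].
#' @param n number of cells.
#' @param config an [imaging_config()].
#' @param seed integer seed (fully determines truths, placement and noise).
#' @param noise render with noise (default) or noise-free.
#' @param duty fraction of channel/frame slots to fill, in (0, 1], or `NULL`
#'   (default) to derive it from the population's expected cell extent.
#' @return A list with `frames` (a lazy [frame_sequence()]) and `manifest`
#'   (a `truth_manifest` data frame, one row per rendered cell).
#' @export
simulate_cells <- function(spec, n, config = imaging_config(), seed = 1,
                           noise = TRUE, duty = NULL) {
  truth <- sample_population(spec, n, seed = seed)
  nch <- config$n_channels
  if (is.null(duty)) {
    # expected flow-axis extent of a large cell vs its placement band
    band <- .safe_band_um(truth, config, margin_px = 3)
    extent <- (config$roi_height_px - 6) * config$pixel_size_um -
      (band[, "hi"] - band[, "lo"])
    occ <- stats::quantile(pmin(1, extent / pmax(band[, "hi"] - band[, "lo"], 1e-9)),
                           0.9, names = FALSE)
    duty <- min(1, 0.35 / max(occ, 0.05))
  }
  stopifnot(duty > 0, duty <= 1)
  stride <- max(1L, as.integer(ceiling(1 / duty - 1e-9)))
  # cycle channels independently of the frame stride so every channel is used
  # and each channel sees a cell only every `stride`-th frame
  j <- seq_len(n) - 1L
  truth$channel_id <- as.integer(j %% nch + 1L)
  truth$frame_index <- as.integer((j * stride) %/% nch + 1L)
  pitch_um <- config$roi_width_px / nch * config$pixel_size_um
  jitter_sd_um <- config$pixel_size_um  # lateral focusing jitter ~1 px
  cx <- config$channel_centers_px[truth$channel_id] * config$pixel_size_um
  truth$x_um <- cx + pmin(pmax(rnorm(n, 0, jitter_sd_um), -pitch_um / 4), pitch_um / 4)
  band <- .safe_band_um(truth, config, margin_px = 3)
  truth$y_um <- runif(n, band[, "lo"], band[, "hi"])
  truth$border_clipped <- FALSE
  attr(truth, "n_frames") <- max(truth$frame_index)
  manifest <- .finish_manifest(truth, config, seed, list(spec), 1)
  list(frames = .manifest_sequence(manifest, config, seed, noise),
       manifest = manifest)
}

#' Simulate a Poisson-arrival stream of mixed populations
#'
#' Cells arrive independently in each channel as a Poisson process; each
#' arrival is assigned to a population by the mixture weights (supporting
#' spiking ratios such as 1:1000 or 1:10000), placed laterally around its
#' channel centreline, and rendered in the frame during which it transits the
#' ROI. The returned manifest lists every rendered cell exactly once; the
#' seed fully determines manifest and frames.
#'
#' @param specs a [population_spec()] or list of them.
#' @param weights mixture weights (must sum to 1).
#' @param arrival_rate_per_channel mean arrivals per channel per second.
#' @param duration_s stream duration (s).
#' @param config an [imaging_config()].
#' @param seed integer seed.
#' @param border_mode `"safe"` keeps every cell clear of the ROI border;
#'   `"full"` draws positions over the whole ROI height so border-clipped
#'   cells occur and are flagged in the manifest.
#' @param noise render with noise.
#' @return A list with `frames` (lazy [frame_sequence()]) and `manifest`.
#' @export
simulate_stream <- function(specs, weights = 1, arrival_rate_per_channel,
                            duration_s, config = imaging_config(), seed = 1,
                            border_mode = c("safe", "full"), noise = TRUE) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  border_mode <- match.arg(border_mode)
  stopifnot(length(weights) == length(specs),
            abs(sum(weights) - 1) < 1e-9,
            arrival_rate_per_channel > 0, duration_s > 0)
  set.seed(as.integer(seed))
  nch <- config$n_channels
  n_frames <- max(1L, as.integer(ceiling(duration_s * config$frame_rate_hz)))
  counts <- rpois(nch, arrival_rate_per_channel * duration_s)
  total <- sum(counts)
  if (total == 0) {
    empty <- sample_population(specs[[1]], 1)[0, ]
    empty$channel_id <- integer(0); empty$frame_index <- integer(0)
    empty$x_um <- numeric(0); empty$y_um <- numeric(0)
    empty$border_clipped <- logical(0)
    attr(empty, "n_frames") <- n_frames
    manifest <- .finish_manifest(empty, config, seed, specs, weights)
    return(list(frames = .manifest_sequence(manifest, config, seed, noise),
                manifest = manifest))
  }
  channel <- rep(seq_len(nch), counts)
  tarr <- runif(total, 0, duration_s)
  pop <- sample.int(length(specs), total, replace = TRUE, prob = weights)
  # draw truths per population (RNG continues on the stream seed)
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    nk <- sum(pop == k)
    if (nk > 0) rows[[k]] <- sample_population(specs[[k]], nk)
  }
  truth <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ord <- integer(total)
  ord[order(pop)] <- seq_len(total)  # map interleaved arrivals to stacked rows
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  truth$channel_id <- as.integer(channel)
  truth$frame_index <- pmin(as.integer(floor(tarr * config$frame_rate_hz)) + 1L,
                            n_frames)
  pitch_um <- config$roi_width_px / nch * config$pixel_size_um
  cx <- config$channel_centers_px[truth$channel_id] * config$pixel_size_um
  truth$x_um <- cx + pmin(pmax(rnorm(total, 0, config$pixel_size_um),
                               -pitch_um / 4), pitch_um / 4)
  if (border_mode == "safe") {
    band <- .safe_band_um(truth, config, margin_px = 3)
    truth$y_um <- runif(total, band[, "lo"], band[, "hi"])
    truth$border_clipped <- FALSE
  } else {
    H_um <- config$roi_height_px * config$pixel_size_um
    truth$y_um <- runif(total, 0, H_um)
    band <- .safe_band_um(truth, config, margin_px = 3)
    truth$border_clipped <- truth$y_um < band[, "lo"] | truth$y_um > band[, "hi"]
  }
  attr(truth, "n_frames") <- n_frames
  manifest <- .finish_manifest(truth, config, seed, specs, weights)
  list(frames = .manifest_sequence(manifest, config, seed, noise),
       manifest = manifest)
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest a `truth_manifest`.
#' @param path output path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest data frame (generator attributes restored from JSON).
#' @export
write_manifest <- function(manifest, path) {
  cfg <- attr(manifest, "config")
  specs <- attr(manifest, "specs")
  obj <- list(
    schema = "vdcyto_manifest_v1",
    seed = attr(manifest, "seed"),
    n_frames = attr(manifest, "n_frames"),
    weights = attr(manifest, "weights"),
    config = unclass(cfg),
    specs = lapply(specs, unclass),
    cells = as.data.frame(unclass(manifest), stringsAsFactors = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "vdcyto_manifest_v1")) {
    stop("not a vdcyto manifest (schema mismatch)")
  }
  truth <- as.data.frame(obj$cells, stringsAsFactors = FALSE)
  attr(truth, "n_frames") <- obj$n_frames
  cfg <- obj$config; class(cfg) <- "imaging_config"
  specs <- lapply(obj$specs, function(s) { class(s) <- "population_spec"; s })
  .finish_manifest(truth, cfg, obj$seed, specs, obj$weights)
}
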