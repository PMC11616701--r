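# Detection pipeline: background estimation, segmentation with sub-pixel
# contour extraction, per-cell feature measurement, presence filtering.

#' Detection configuration
#'
#' @param background_frames number of frames sampled for background
#'   estimation.
#' @param median_kernel_px odd median-filter kernel width (>= 1; 1 disables).
#' @param threshold absolute threshold (counts) on the background-subtracted
#'   image, or `NULL` to use `threshold_k` times the estimated noise SD.
#' @param threshold_k multiplier for the noise-SD threshold rule.
#' @param min_area_um2,max_area_um2 accepted projected-area range.
#' @param area_ratio_max maximum convex-hull-to-contour area ratio; larger
#'   values indicate concave debris rather than a cell.
#' @param border_margin_px contours whose bounding box comes within this many
#'   pixels of the ROI edge are rejected as clipped.
#' @param polarity `"dark"` for dark cells on a bright background (the
#'   bright-field case), `"bright"` for the inverse.
#' @param fourier_harmonics harmonics kept when regularising detected
#'   contours (see Details); 0 disables regularisation.
#' @param refine_subpixel re-localise contour vertices at the local
#'   half-amplitude crossing along the edge normal and undo the second-order
#'   curvature bias of blurred edges (see Details).
#' @param background_method `"median"` (robust to transiting cells) or
#'   `"mean"`.
#'
#' @details Candidate masks are built on the median-filtered
#' background-subtracted image, but the sub-pixel iso-contour is traced on the
#' unfiltered subtracted image at the threshold level and then projected onto
#' a truncated Fourier basis (least squares on an arc-length resampled closed
#' curve). The projection suppresses pixel-noise jitter, which otherwise
#' inflates the perimeter and hence the deformability, without the shrinkage
#' bias of kernel smoothing. Measurement functions themselves never smooth.
#' @return A `detection_config` object.
#' @export
detection_config <- function(background_frames = 100L, median_kernel_px = 3L,
                             threshold = NULL, threshold_k = 6,
                             min_area_um2 = 10, max_area_um2 = 700,
                             area_ratio_max = 1.25, border_margin_px = 3L,
                             polarity = c("dark", "bright"),
                             fourier_harmonics = 8L,
                             refine_subpixel = TRUE,
                             background_method = c("median", "mean")) {
  polarity <- match.arg(polarity)
  background_method <- match.arg(background_method)
  stopifnot(median_kernel_px >= 1, median_kernel_px %% 2 == 1,
            min_area_um2 < max_area_um2, area_ratio_max >= 1,
            border_margin_px >= 0, threshold_k > 0, fourier_harmonics >= 0)
  structure(list(background_frames = as.integer(background_frames),
                 median_kernel_px = as.integer(median_kernel_px),
                 threshold = threshold, threshold_k = threshold_k,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 area_ratio_max = area_ratio_max,
                 border_margin_px = as.integer(border_margin_px),
                 polarity = polarity,
                 fourier_harmonics = as.integer(fourier_harmonics),
                 refine_subpixel = isTRUE(refine_subpixel),
                 background_method = background_method),
            class = "detection_config")
}

#' Estimate the static background of a sequence
#'
#' Samples frames evenly across the sequence and combines them per pixel with
#' the configured estimator (median by default, which at low per-pixel cell
#' occupancy recovers the cell-free background; mean follows the classical
#' average-of-frames rule). Also estimates the temporal noise SD.
#'
#' @param frames a [frame_sequence()].
#' @param config a [detection_config()].
#' @param noise_sd_image if `TRUE`, also return the per-pixel noise-SD image.
#' @return List with `background` (numeric matrix), `noise_sd` (scalar,
#'   robust median of per-pixel SDs), and optionally `noise_sd_image`.
#'   A single-frame sequence yields that frame with a warning.
#' @export
estimate_background <- function(frames, config = detection_config(),
                                noise_sd_image = FALSE) {
  n <- n_frames(frames)
  if (n < 1) stop("cannot estimate a background from an empty sequence")
  if (n == 1) {
    warning("single-frame sequence: background equals that frame")
    f <- get_frame(frames, 1)
    out <- list(background = f + 0.0, noise_sd = 0)
    if (noise_sd_image) out$noise_sd_image <- matrix(0, nrow(f), ncol(f))
    return(out)
  }
  s <- min(n, config$background_frames)
  idx <- unique(round(seq(1, n, length.out = s)))
  f1 <- get_frame(frames, idx[1])
  arr <- matrix(0, length(idx), length(f1))
  for (k in seq_along(idx)) arr[k, ] <- as.vector(get_frame(frames, idx[k]))
  bg <- if (config$background_method == "median") {
    apply(arr, 2, median)
  } else {
    colMeans(arr)
  }
  background <- matrix(bg, nrow(f1), ncol(f1))
  # robust scale of the temporal fluctuations, pooled over a pixel subsample;
  # the MAD is interpolated across integer count bins so coarse quantisation
  # at small sigma does not bias it
  samp <- unique(round(seq(1, ncol(arr), length.out = min(4000L, ncol(arr)))))
  sub <- arr[, samp, drop = FALSE]
  med <- apply(sub, 2, median)
  dev <- abs(sweep(sub, 2, med))
  out <- list(background = background, noise_sd = .robust_sigma(as.vector(dev)))
  if (noise_sd_image) {
    devf <- abs(sweep(arr, 2, apply(arr, 2, median)))
    out$noise_sd_image <- matrix(apply(devf, 2, .robust_sigma),
                                 nrow(f1), ncol(f1))
  }
  out
}

# scale estimate from absolute deviations: median interpolated over integer
# bins (binned-continuous reading of count data), scaled by the normal
# consistency constant
.robust_sigma <- function(a) {
  if (!length(a)) return(0)
  k <- 0
  flo <- mean(a <= k + 0.5)
  if (flo >= 1) return(0)
  while (TRUE) {
    fhi <- mean(a <= k + 1.5)
    if (fhi >= 0.5 || k > max(a)) break
    flo <- fhi
    k <- k + 1
  }
  if (flo >= 0.5) {
    m <- 0.5 * 0.5 / flo  # median falls inside the first bin [0, 0.5]
  } else {
    m <- (k + 0.5) + (0.5 - flo) / max(fhi - flo, 1e-12)
  }
  1.4826 * m
}

# count of TRUE values in the (2r+1)x(2r+1) window around each pixel
# (replicated borders), vectorised over shifted matrices
.neighbour_count <- function(b, r) {
  H <- nrow(b); W <- ncol(b)
  ri <- function(s) pmin(pmax(seq_len(H) + s, 1L), H)
  ci <- function(s) pmin(pmax(seq_len(W) + s, 1L), W)
  cnt <- matrix(0L, H, W)
  for (dr in -r:r) for (dc in -r:r) cnt <- cnt + b[ri(dr), ci(dc)]
  cnt
}

# bilinear interpolation of matrix d (rows = y) at 0-based pixel coords
.bilinear <- function(d, x, y) {
  H <- nrow(d); W <- ncol(d)
  x <- pmin(pmax(x, 0), W - 1 - 1e-9)
  y <- pmin(pmax(y, 0), H - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  d[i00] * (1 - fx) * (1 - fy) + d[i01] * fx * (1 - fy) +
    d[i10] * (1 - fx) * fy + d[i11] * fx * fy
}

# tangents, outward normals, curvature and arc steps of a smooth closed polygon
.polygon_frame <- function(P) {
  n <- nrow(P)
  nx <- P[c(2:n, 1), ] - P[c(n, 1:(n - 1)), ]  # central differences
  tx <- nx[, 1] / 2; ty <- nx[, 2] / 2
  ax <- P[c(2:n, 1), 1] - 2 * P[, 1] + P[c(n, 1:(n - 1)), 1]
  ay <- P[c(2:n, 1), 2] - 2 * P[, 2] + P[c(n, 1:(n - 1)), 2]
  sp2 <- tx^2 + ty^2
  kappa <- (tx * ay - ty * ax) / pmax(sp2^1.5, 1e-12)
  # outward normal: for a counter-clockwise polygon the outward side is
  # (ty, -tx); orient by signed area
  x <- P[, 1]; y <- P[, 2]
  sa <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  sgn <- if (sa > 0) 1 else -1
  nlen <- sqrt(pmax(sp2, 1e-12))
  list(normal = cbind(sgn * ty, -sgn * tx) / nlen,
       kappa = sgn * kappa,
       ds = nlen)
}

# sub-pixel edge refinement: move each vertex to the crossing of the local
# half-amplitude along its normal, estimate the edge blur sigma from the
# pooled profile, and undo the second-order curvature bias sigma^2*kappa/2
# of a blurred curved edge. Operates on, and returns, a closed polygon in
# 0-based pixel coordinates; d is the raw background-subtracted image.
.refine_contour <- function(P, d, K) {
  n <- nrow(P)
  if (n < 16) return(P)
  fr <- .polygon_frame(P)
  r_eq <- sqrt(polygon_area(P) / pi)
  t_out <- 2.5
  t_in <- -min(2.5, max(0.8, 0.6 * r_eq))
  ts <- seq(t_in, t_out, by = 0.25)
  nt <- length(ts)
  px <- rep(P[, 1], times = nt) + rep(ts, each = n) * rep(fr$normal[, 1], times = nt)
  py <- rep(P[, 2], times = nt) + rep(ts, each = n) * rep(fr$normal[, 2], times = nt)
  prof <- matrix(.bilinear(d, px, py), n, nt)  # rows: vertices, cols: offsets
  h_in <- rowMeans(prof[, ts <= t_in + 0.5, drop = FALSE])
  h_out <- rowMeans(prof[, ts >= t_out - 0.5, drop = FALSE])
  amp <- h_in - h_out
  ok <- amp > .Machine$double.eps
  if (mean(ok) < 0.5) return(P)
  # per-vertex crossing of the local mid level (monotone segment around 0)
  mid <- (h_in + h_out) / 2
  shift <- rep(0, n)
  for (i in which(ok)) {
    below <- prof[i, ] <= mid[i]
    j <- which(below & !c(FALSE, below[-nt]))  # first crossing from above
    j <- j[j > 1]
    if (!length(j)) next
    j <- j[which.min(abs(ts[j]))]
    p1 <- prof[i, j - 1]; p2 <- prof[i, j]
    frac <- if (p1 == p2) 0 else (p1 - mid[i]) / (p1 - p2)
    shift[i] <- ts[j - 1] + frac * (ts[j] - ts[j - 1])
  }
  shift <- pmin(pmax(shift, -1), 1)
  P2 <- P + shift * fr$normal
  P2 <- .fourier_regularize(P2, K)
  # blur SD from the pooled normalised profile (quartile width of an erf edge)
  pn <- colMeans((prof[ok, , drop = FALSE] - h_out[ok]) / amp[ok])
  q <- function(level) {
    below <- pn <= level
    j <- which(below & !c(FALSE, below[-nt]))
    j <- j[j > 1]
    if (!length(j)) return(NA_real_)
    j <- j[which.min(abs(ts[j]))]
    p1 <- pn[j - 1]; p2 <- pn[j]
    ts[j - 1] + (p1 - level) / (p1 - p2) * (ts[j] - ts[j - 1])
  }
  t75 <- q(0.75); t25 <- q(0.25)
  sigma <- if (is.na(t25) || is.na(t75) || t25 <= t75) 0.8 else (t25 - t75) / 1.349
  sigma <- min(max(sigma, 0.3), 3)
  fr2 <- .polygon_frame(P2)
  delta <- pmin(pmax(sigma^2 * fr2$kappa / 2, -0.5), 0.5)
  P3 <- P2 + delta * fr2$normal
  P3 <- .fourier_regularize(P3, K)
  attr(P3, "edge_sigma") <- sigma
  P3
}

# least-squares projection of a closed polyline onto K Fourier harmonics,
# after resampling to uniform arc length (power-of-two M for the FFT).
.fourier_regularize <- function(P, K) {
  n <- nrow(P)
  if (n < max(16L, 2L * K + 2L) || K <= 0) return(P)
  seg <- sqrt(diff(c(P[, 1], P[1, 1]))^2 + diff(c(P[, 2], P[1, 2]))^2)
  L <- sum(seg)
  if (L <= 0) return(P)
  M <- max(64L, 2L^ceiling(log2(L / 0.5)))
  s <- cumsum(c(0, seg))
  keep <- c(TRUE, diff(s[seq_len(n)]) > 1e-12)
  su <- seq(0, L, length.out = M + 1L)[-(M + 1L)]
  xs <- c(P[keep, 1], P[1, 1]); ys <- c(P[keep, 2], P[1, 2])
  sk <- c(s[seq_len(n)][keep], L)
  xr <- approx(sk, xs, xout = su)$y
  yr <- approx(sk, ys, xout = su)$y
  trunc1 <- function(v) {
    f <- fft(v)
    f[(K + 2L):(M - K)] <- 0i
    Re(fft(f, inverse = TRUE)) / M
  }
  cbind(trunc1(xr), trunc1(yr))
}

#' Segment one frame into candidate cell contours
#'
#' Implements the core pipeline: polarity-aware background subtraction, median
#' filtering, binary thresholding, 8-connected component labelling, and
#' sub-pixel contour extraction by iso-level tracing at the threshold level
#' (marching-squares with linear interpolation). One outer closed contour is
#' returned per component; holes are ignored.
#'
#' @param frame integer matrix (rows = y).
#' @param background background matrix from [estimate_background()].
#' @param config a [detection_config()].
#' @param noise_sd noise SD used when `config$threshold` is `NULL`.
#' @return List of two-column contour matrices in 0-based pixel coordinates
#'   (x, y), each carrying the threshold used as attribute `"level"`. A
#'   saturated frame (>= 99 % of pixels at the maximum value) returns an empty
#'   list with attribute `"rejected" = "saturated"`.
#' @export
segment_frame <- function(frame, background, config = detection_config(),
                          noise_sd = NULL) {
  stopifnot(all(dim(frame) == dim(background)))
  maxval <- max(2^8 - 1, max(frame))
  if (mean(frame >= maxval) >= 0.99) {
    out <- list()
    attr(out, "rejected") <- "saturated"
    return(out)
  }
  d <- if (config$polarity == "dark") background - frame else frame - background
  thr <- if (!is.null(config$threshold)) config$threshold else {
    if (is.null(noise_sd)) stop("threshold is k x noise SD but no noise_sd supplied")
    config$threshold_k * noise_sd
  }
  # mask = (median_kxk(d) > thr); for the binary mask this is exactly a
  # neighbour count (median > thr iff more than half the window exceeds thr),
  # which avoids computing median values never used elsewhere
  mask <- if (config$median_kernel_px > 1) {
    k <- config$median_kernel_px
    .neighbour_count(d > thr, (k - 1L) %/% 2L) > (k * k) %/% 2L
  } else {
    d > thr
  }
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  min_px <- max(12L, floor(0.3 * config$min_area_um2))  # coarse pre-filter
  out <- list()
  comp <- split(which(lab > 0), lab[lab > 0])
  H <- nrow(frame); W <- ncol(frame)
  for (ci in comp) {
    if (length(ci) < min_px) next
    rows <- ((ci - 1L) %% H) + 1L
    cols <- ((ci - 1L) %/% H) + 1L
    y0 <- max(1L, min(rows) - 4L); y1 <- min(H, max(rows) + 4L)
    x0 <- max(1L, min(cols) - 4L); x1 <- min(W, max(cols) + 4L)
    w <- d[y0:y1, x0:x1, drop = FALSE]
    wp <- matrix(-Inf, nrow(w) + 2L, ncol(w) + 2L)
    wp[2:(nrow(w) + 1L), 2:(ncol(w) + 1L)] <- w
    wp[!is.finite(wp)] <- min(w, thr - 1)
    cls <- contourLines(x = seq_len(nrow(wp)), y = seq_len(ncol(wp)),
                        z = wp, levels = thr)
    if (!length(cls)) next
    areas <- vapply(cls, function(cc) {
      polygon_area(cbind(cc$x, cc$y))
    }, numeric(1))
    cc <- cls[[which.max(areas)]]
    m <- length(cc$x)
    if (m > 2 && cc$x[1] == cc$x[m] && cc$y[1] == cc$y[m]) m <- m - 1L
    # window rows map to contour x, window cols to contour y;
    # convert to 0-based frame pixel coordinates (x = column, y = row)
    P <- cbind(x = cc$y[seq_len(m)] + x0 - 3L, y = cc$x[seq_len(m)] + y0 - 3L)
    P <- .fourier_regularize(P, config$fourier_harmonics)
    if (config$refine_subpixel && config$fourier_harmonics > 0) {
      P <- .refine_contour(P, d, config$fourier_harmonics)
    }
    colnames(P) <- c("x", "y")
    attr(P, "level") <- thr
    out[[length(out) + 1L]] <- P
  }
  out
}

# pixel centres (0-based coords) strictly inside a closed polygon
.pixels_inside <- function(contour, H, W) {
  x0 <- max(0L, floor(min(contour[, 1]))); x1 <- min(W - 1L, ceiling(max(contour[, 1])))
  y0 <- max(0L, floor(min(contour[, 2]))); y1 <- min(H - 1L, ceiling(max(contour[, 2])))
  if (x1 < x0 || y1 < y0) return(NULL)
  gx <- x0:x1; gy <- y0:y1
  pts <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  bnd <- rbind(contour, contour[1, , drop = FALSE])
  ins <- mgcv::in.out(bnd, pts)
  if (!any(ins)) return(NULL)
  pts[ins, , drop = FALSE]
}

#' Measure one cell from its contour
#'
#' Computes the per-cell features: projected area (shoelace), perimeter
#' (polyline length), deformability `1 - 2*sqrt(pi*A)/l`, brightness (mean of
#' original-frame pixel intensities whose centres fall inside the contour),
#' aspect ratio (major/minor axis of the moment-equivalent ellipse of the
#' enclosed pixel set), area ratio (convex-hull area / contour area), centroid
#' of the enclosed pixel set, and the channel assignment. Interior holes are
#' implicitly filled since only the outer contour is used.
#'
#' @param contour two-column matrix, 0-based pixel coordinates (x, y), closed
#'   implicitly, simple, at least 8 vertices.
#' @param frame original intensity frame (not background-subtracted).
#' @param config a [detection_config()] (used for bookkeeping only).
#' @param calibration an [imaging_config()] supplying `pixel_size_um` and
#'   `channel_centers_px`.
#' @param frame_index frame number stored in the record.
#' @return One-row `results_table` data frame (a `CellRecord`). Degenerate
#'   contours yield a rejected record with reason `"degenerate"`.
#' @export
measure_cell <- function(contour, frame, config = detection_config(),
                         calibration = imaging_config(), frame_index = NA_integer_) {
  px <- calibration$pixel_size_um
  A_px <- polygon_area(contour)
  rec <- empty_results_table()[0, ]
  if (!is.matrix(contour) || nrow(contour) < 8 || A_px <= 0) {
    rec[1, ] <- list(frame_index, NA_integer_, NA_real_, NA_real_, NA_real_,
                     NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                     FALSE, "degenerate")
    return(rec)
  }
  l_px <- polygon_perimeter(contour)
  D <- deformability(A_px, l_px)
  pix <- .pixels_inside(contour, nrow(frame), ncol(frame))
  if (is.null(pix)) {
    cen <- polygon_centroid(contour)
    brightness <- NA_real_
    aspect <- 1
  } else {
    brightness <- mean(frame[cbind(pix[, 2] + 1L, pix[, 1] + 1L)])
    cen <- colMeans(pix)
    if (nrow(pix) > 2) {
      cv <- cov(pix) + diag(2) / 12  # pixel-bin variance correction
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      aspect <- sqrt(max(ev) / max(min(ev), .Machine$double.eps))
    } else aspect <- 1
  }
  hull <- contour[chull(contour), , drop = FALSE]
  area_ratio <- polygon_area(hull) / A_px
  channel <- if (length(calibration$channel_centers_px)) {
    which.min(abs(calibration$channel_centers_px - cen[1]))
  } else NA_integer_
  rec[1, ] <- list(as.integer(frame_index), as.integer(channel),
                   cen[1] * px, cen[2] * px,
                   A_px * px^2, l_px * px, D, brightness,
                   max(aspect, 1), area_ratio, TRUE, "")
  attr(rec, "contour") <- contour
  rec
}

#' Apply the presence/quality filter to a measured record
#'
#' Rejects records whose area is outside the configured range, whose
#' hull-to-contour area ratio marks them as concave debris, or whose contour
#' comes within the border margin of the ROI edge (clipped cell). Reasons are
#' machine-readable: `"area_min"`, `"area_max"`, `"area_ratio"`, `"border"`.
#'
#' @param record one-row record from [measure_cell()] (with its `"contour"`
#'   attribute).
#' @param config a [detection_config()].
#' @param calibration an [imaging_config()] giving the ROI dimensions.
#' @return The record with `accepted`/`reject_reason` updated.
#' @export
presence_filter <- function(record, config = detection_config(),
                            calibration = imaging_config()) {
  if (!record$accepted[1]) return(record)
  reasons <- character(0)
  if (record$area_um2[1] < config$min_area_um2) reasons <- c(reasons, "area_min")
  if (record$area_um2[1] > config$max_area_um2) reasons <- c(reasons, "area_max")
  if (record$area_ratio[1] > config$area_ratio_max) reasons <- c(reasons, "area_ratio")
  contour <- attr(record, "contour")
  if (!is.null(contour)) {
    m <- config$border_margin_px
    if (min(contour[, 1]) < m || min(contour[, 2]) < m ||
        max(contour[, 1]) > calibration$roi_width_px - 1 - m ||
        max(contour[, 2]) > calibration$roi_height_px - 1 - m) {
      reasons <- c(reasons, "border")
    }
  }
  if (length(reasons)) {
    record$accepted <- FALSE
    record$reject_reason <- paste(reasons, collapse = ";")
  }
  record
}

# measure + filter all candidates of one frame (shared by batch & streaming)
.process_one_frame <- function(frame, background, dconfig, iconfig, i,
                               noise_sd) {
  contours <- segment_frame(frame, background, dconfig, noise_sd)
  if (identical(attr(contours, "rejected"), "saturated")) {
    return(structure(list(), rejected = "saturated"))
  }
  lapply(contours, function(ct) {
    presence_filter(measure_cell(ct, frame, dconfig, iconfig, i),
                    dconfig, iconfig)
  })
}

#' Process a whole frame sequence into a results table
#'
#' Estimates (or takes) a background, then segments, measures, and filters
#' every frame in acquisition order. Frame-level rejections (saturation) are
#' logged and skipped, never fatal. Per-stage counters are attached as
#' attribute `"counters"` and optionally appended to a log file.
#'
#' @param frames a [frame_sequence()].
#' @param config a [detection_config()].
#' @param calibration an [imaging_config()]; defaults to the sequence's own.
#' @param background optional precomputed [estimate_background()] result.
#' @param log_path optional path; per-stage counters are appended as text.
#' @return A `results_table` with one row per detected candidate.
#' @export
process_sequence <- function(frames, config = detection_config(),
                             calibration = NULL, background = NULL,
                             log_path = NULL) {
  if (is.null(calibration)) calibration <- frames$config
  if (is.null(calibration)) calibration <- imaging_config()
  nf <- n_frames(frames)
  if (nf == 0) return(empty_results_table())
  if (is.null(background)) background <- estimate_background(frames, config)
  rows <- vector("list", nf)
  counters <- c(frames = nf, frames_rejected = 0L, candidates = 0L,
                accepted = 0L)
  reject_reasons <- list()
  for (i in seq_len(nf)) {
    recs <- .process_one_frame(get_frame(frames, i), background$background,
                               config, calibration, i, background$noise_sd)
    if (identical(attr(recs, "rejected"), "saturated")) {
      counters["frames_rejected"] <- counters["frames_rejected"] + 1L
      next
    }
    if (length(recs)) {
      counters["candidates"] <- counters["candidates"] + length(recs)
      recs <- lapply(recs, function(r) { attr(r, "contour") <- NULL; r })
      rows[[i]] <- do.call(rbind, recs)
    }
  }
  out <- do.call(rbind, c(list(empty_results_table()), rows[!vapply(rows, is.null, logical(1))]))
  counters["accepted"] <- sum(out$accepted)
  rej <- table(out$reject_reason[!out$accepted])
  attr(out, "counters") <- counters
  attr(out, "reject_reasons") <- rej
  class(out) <- c("results_table", "data.frame")
  if (!is.null(log_path)) {
    lines <- c(sprintf("vdcyto process: frames=%d rejected_frames=%d candidates=%d accepted=%d",
                       counters["frames"], counters["frames_rejected"],
                       counters["candidates"], counters["accepted"]),
               sprintf("  reject[%s]=%d", names(rej), as.integer(rej)))
    cat(lines, file = log_path, sep = "\n", append = TRUE)
  }
  out
}

#' Estimate per-cell velocities by frame-to-frame matching
#'
#' Matches records of consecutive frames within the same channel by nearest
#' centroid, gated by a maximum displacement along the flow axis and a small
#' transverse tolerance; velocity is `displacement x frame rate`. Cells that
#' appear in a single frame, or whose match is ambiguous (two candidates in
#' the gate), get no estimate.
#'
#' @param records a `results_table`.
#' @param calibration an [imaging_config()] (frame rate, pixel size).
#' @param max_displacement_px gate along the flow axis.
#' @param transverse_gate_px transverse matching tolerance.
#' @return The table with a `velocity_mps` column added (`NA` where no
#'   estimate).
#' @export
estimate_velocity <- function(records, calibration = imaging_config(),
                              max_displacement_px = 60,
                              transverse_gate_px = 4) {
  records[["velocity_mps"]] <- rep(NA_real_, nrow(records))
  if (nrow(records) == 0) return(records)
  px <- calibration$pixel_size_um
  for (i in seq_len(nrow(records))) {
    if (!records$accepted[i]) next
    nxt <- which(records$frame_index == records$frame_index[i] + 1L &
                 records$channel_id == records$channel_id[i] &
                 records$accepted)
    if (!length(nxt)) next
    dy <- (records$centroid_y_um[nxt] - records$centroid_y_um[i]) / px
    dx <- abs(records$centroid_x_um[nxt] - records$centroid_x_um[i]) / px
    cand <- nxt[dy >= 0 & dy <= max_displacement_px & dx <= transverse_gate_px]
    if (length(cand) != 1L) next  # unmatched or ambiguous
    disp_um <- records$centroid_y_um[cand] - records$centroid_y_um[i]
    records$velocity_mps[i] <- disp_um * 1e-6 * calibration$frame_rate_hz
  }
  records
}
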