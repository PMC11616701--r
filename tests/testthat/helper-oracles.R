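# Shared fixtures and independent oracles used across test files.

# small imaging configuration for fast unit tests (two channels)
quick_config <- function(...) {
  imaging_config(roi_width_px = 256L, roi_height_px = 80L, n_channels = 2L, ...)
}

# regular-polygon circle contour in pixel coordinates
circle_contour <- function(r_px, cx = 0, cy = 0, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r_px * cos(th), y = cy + r_px * sin(th))
}

# axis-aligned ellipse contour
ellipse_contour <- function(a_px, b_px, cx = 0, cy = 0, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + a_px * cos(th), y = cy + b_px * sin(th))
}

# square contour with densified edges (vertex spacing ~0.5 px)
square_contour <- function(side_px, x0 = 0, y0 = 0) {
  corners <- rbind(c(0, 0), c(side_px, 0), c(side_px, side_px), c(0, side_px))
  out <- NULL
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[(i %% 4) + 1, ]
    m <- max(2L, ceiling(side_px / 0.5))
    tt <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    out <- rbind(out, cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2])))
  }
  cbind(x = out[, 1] + x0, y = out[, 2] + y0)
}

# crescent (outer arc minus offset inner arc): strongly concave test object
crescent_contour <- function(r_out = 12, r_in = 10, offset = 5, cx = 0, cy = 0) {
  th1 <- seq(-2.2, 2.2, length.out = 80)
  outer_arc <- cbind(cx + r_out * cos(th1), cy + r_out * sin(th1))
  th2 <- rev(th1)
  inner_arc <- cbind(cx + offset + r_in * cos(th2), cy + r_in * sin(th2))
  P <- rbind(outer_arc, inner_arc)
  colnames(P) <- c("x", "y")
  P
}

# brute-force two-sided Mann-Whitney P by complete enumeration (no ties)
mwu_exact_bruteforce <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) sum(rank(vals)[ii]) - nx * (nx + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# one full end-to-end population recovery, memoised across test files
.recovery_cache <- new.env(parent = emptyenv())
cached_recovery <- function(name, n = 5000, seed = 20240 + match(name, names(calibrated_populations()))) {
  key <- paste(name, n, seed, sep = "_")
  if (is.null(.recovery_cache[[key]])) {
    spec <- calibrated_populations()[[name]]
    .recovery_cache[[key]] <- recover_population(spec, n = n, seed = seed)$summary
  }
  .recovery_cache[[key]]
}
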