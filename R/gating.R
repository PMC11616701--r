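# Density representations in (area, deformability) space, half-maximum
# density contours, gates, and rare-cell quantification.

.scott_bw <- function(v, n) sd(v) * n^(-1 / 6)  # per-axis 2-D Scott rule

#' Build a 2-D density map over (area, deformability)
#'
#' @param points two-column matrix or data frame: area (um^2) then
#'   deformability. A `results_table` may be passed directly (accepted rows
#'   are used).
#' @param method `"histogram"` (bin counts normalised to a density) or
#'   `"kde"` (Gaussian product kernel evaluated on the grid).
#' @param bins grid resolution (length-1 or -2); defaults to 64 for the
#'   histogram and 128 for the KDE (finer grid keeps the quadrature error of
#'   the smooth density small).
#' @param bandwidth per-axis kernel SD for `"kde"`; default Scott's rule.
#' @param range list with `x` and `y` ranges; default spans the robust
#'   1st-99th percentile range (expanded for the KDE by 3 bandwidths).
#'   Histogram counts falling outside the range are clamped to edge bins so
#'   the density still integrates to 1.
#' @return A `density_grid`: list with `x`, `y` (bin/grid centres), `z`
#'   (density), `method`, `params`, `n_points`.
#' @export
density_map <- function(points, method = c("histogram", "kde"), bins = NULL,
                        bandwidth = NULL, range = NULL) {
  method <- match.arg(method)
  pts <- .as_points(points)
  if (nrow(pts) < 10) stop("density_map needs at least 10 points")
  if (is.null(bins)) bins <- if (method == "kde") 128L else 64L
  bins <- rep(as.integer(bins), length.out = 2)
  ax_names <- c("area", "deformability")
  for (k in 1:2) {
    if (method == "kde" && sd(pts[, k]) == 0 && is.null(bandwidth)) {
      stop(sprintf("degenerate axis '%s': zero variance, KDE bandwidth undefined",
                   ax_names[k]))
    }
  }
  n <- nrow(pts)
  if (is.null(range)) {
    probs <- if (method == "kde") c(0.001, 0.999) else c(0.01, 0.99)
    qs <- apply(pts, 2, stats::quantile, probs = probs, names = FALSE)
    if (method == "kde") {
      bw <- if (is.null(bandwidth)) c(.scott_bw(pts[, 1], n), .scott_bw(pts[, 2], n)) else rep(bandwidth, length.out = 2)
      qs[1, ] <- qs[1, ] - 4 * bw
      qs[2, ] <- qs[2, ] + 4 * bw
    }
    # degenerate (zero-width) axis: unit-width fallback so histograms of
    # identical points still yield a single occupied bin
    for (k in 1:2) if (qs[1, k] >= qs[2, k]) qs[, k] <- qs[1, k] + c(-0.5, 0.5)
    range <- list(x = qs[, 1], y = qs[, 2])
  }
  if (method == "histogram") {
    dx <- diff(range$x) / bins[1]; dy <- diff(range$y) / bins[2]
    ix <- pmin(pmax(floor((pts[, 1] - range$x[1]) / dx), 0), bins[1] - 1)
    iy <- pmin(pmax(floor((pts[, 2] - range$y[1]) / dy), 0), bins[2] - 1)
    z <- matrix(tabulate(ix * bins[2] + iy + 1, nbins = bins[1] * bins[2]),
                nrow = bins[1], byrow = TRUE)
    z <- z / (n * dx * dy)
    grid <- list(x = range$x[1] + (seq_len(bins[1]) - 0.5) * dx,
                 y = range$y[1] + (seq_len(bins[2]) - 0.5) * dy,
                 z = z, method = method,
                 params = list(bins = bins), n_points = n)
  } else {
    bw <- if (is.null(bandwidth)) c(.scott_bw(pts[, 1], n), .scott_bw(pts[, 2], n)) else rep(bandwidth, length.out = 2)
    k <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bw, n = bins,
                     lims = c(range$x, range$y))
    grid <- list(x = k$x, y = k$y, z = k$z, method = method,
                 params = list(bins = bins, bandwidth = bw), n_points = n)
  }
  class(grid) <- "density_grid"
  grid
}

.as_points <- function(points) {
  if (inherits(points, "results_table")) {
    points <- points[points$accepted, c("area_um2", "deformability")]
  }
  m <- as.matrix(points[, 1:2])
  m[complete.cases(m), , drop = FALSE]
}

#' Integrate a density grid
#'
#' Histogram grids are bin-centred, so the rectangle sum is exact; KDE grids
#' are node-centred and use the trapezoid rule.
#'
#' @param grid a `density_grid`.
#' @return Approximate integral of the density over the grid; ~1 for a
#'   normalised density.
#' @export
density_integral <- function(grid) {
  dx <- mean(diff(grid$x)); dy <- mean(diff(grid$y))
  if (identical(grid$method, "histogram")) return(sum(grid$z) * dx * dy)
  wx <- rep(1, length(grid$x)); wx[c(1, length(wx))] <- 0.5
  wy <- rep(1, length(grid$y)); wy[c(1, length(wy))] <- 0.5
  sum(grid$z * outer(wx, wy)) * dx * dy
}

#' Extract iso-contours at a fraction of the maximum density
#'
#' Traces the level set `level * max(density)` by marching squares with
#' linear interpolation. Multiple disjoint regions yield multiple gates.
#'
#' @param grid a `density_grid` with a strictly positive maximum.
#' @param level fraction of the maximum density, in (0, 1]; default 0.5 (the
#'   50 %-density contour used throughout the package's scatterplots).
#' @return List of `gate_region` objects (closed polygons in (area,
#'   deformability) space with level and provenance). `level = 1` returns a
#'   degenerate zero-area gate at the mode.
#' @export
half_max_contour <- function(grid, level = 0.5) {
  if (!(level > 0 && level <= 1)) stop("level must be in (0, 1]")
  zmax <- max(grid$z)
  if (!(zmax > 0)) stop("density grid has no positive maximum")
  cls <- contourLines(grid$x, grid$y, grid$z, levels = level * zmax)
  if (!length(cls)) {
    idx <- which(grid$z == zmax, arr.ind = TRUE)[1, ]
    mode_pt <- c(grid$x[idx[1]], grid$y[idx[2]])
    poly <- rbind(mode_pt, mode_pt, mode_pt)
    return(list(gate_region(poly, level, list(note = "degenerate mode gate"))))
  }
  lapply(cls, function(cc) {
    m <- length(cc$x)
    if (m > 2 && cc$x[1] == cc$x[m] && cc$y[1] == cc$y[m]) m <- m - 1
    gate_region(cbind(cc$x[seq_len(m)], cc$y[seq_len(m)]), level, NULL)
  })
}

#' Construct a gate region
#' @param polygon two-column matrix (area, deformability), simple, closed
#'   implicitly.
#' @param level density level (fraction of max) the polygon was traced at.
#' @param provenance free-form list describing how the gate was derived.
#' @return A `gate_region` object.
#' @export
gate_region <- function(polygon, level = NA_real_, provenance = NULL) {
  polygon <- as.matrix(polygon)
  colnames(polygon) <- c("area_um2", "deformability")
  structure(list(polygon = polygon, level = level, provenance = provenance),
            class = "gate_region")
}

#' @export
print.gate_region <- function(x, ...) {
  cat(sprintf("gate_region: %d vertices at %.0f%%-of-max density; area range [%.1f, %.1f], D range [%.3f, %.3f]\n",
              nrow(x$polygon), 100 * x$level,
              min(x$polygon[, 1]), max(x$polygon[, 1]),
              min(x$polygon[, 2]), max(x$polygon[, 2])))
  invisible(x)
}

#' Derive a gate from a reference population
#'
#' Builds the density of a pure reference sample in (area, deformability)
#' space and takes the largest-area contour at `level` x max density as the
#' gate. The measured gate efficiency (fraction of the reference inside the
#' gate) is stored in the provenance: a half-maximum contour of a roughly
#' Gaussian population contains only about half its mass, so counts gated
#' from a mixture must be rescaled by this efficiency for abundance
#' estimates (see [rare_cell_ratio()]).
#'
#' @param reference_points reference sample (matrix/data frame/`results_table`).
#' @param method density method (`"kde"` default, or `"histogram"`).
#' @param level fraction of maximum density.
#' @param bins,bandwidth passed to [density_map()].
#' @param min_points minimum reference size.
#' @return A `gate_region` with provenance (reference size, method, level,
#'   bandwidth, `gate_efficiency`).
#' @export
derive_gate <- function(reference_points, method = c("kde", "histogram"),
                        level = 0.5, bins = 64, bandwidth = NULL,
                        min_points = 100) {
  method <- match.arg(method)
  pts <- .as_points(reference_points)
  if (nrow(pts) == 0) stop("empty reference population")
  if (nrow(pts) < min_points) {
    stop(sprintf("reference population too small (%d points, below minimum %d)",
                 nrow(pts), min_points))
  }
  grid <- density_map(pts, method = method, bins = bins, bandwidth = bandwidth)
  gates <- half_max_contour(grid, level)
  areas <- vapply(gates, function(g) polygon_area(g$polygon), numeric(1))
  gate <- gates[[which.max(areas)]]
  eff <- mean(apply_gate(pts, gate)$inside)
  gate$provenance <- list(n_reference = nrow(pts), method = method,
                          level = level,
                          bandwidth = grid$params$bandwidth,
                          gate_efficiency = eff)
  gate
}

#' Apply a gate to points
#'
#' Point-in-polygon test with points on the boundary counted as inside (the
#' package's documented convention).
#'
#' @param points matrix/data frame/`results_table` of (area, deformability).
#' @param gate a `gate_region`.
#' @return List with `inside` (logical vector) and `count`.
#' @export
apply_gate <- function(points, gate) {
  pts <- .as_points(points)
  n <- nrow(pts)
  inside <- logical(n)
  if (n == 0) return(list(inside = inside, count = 0L))
  poly <- gate$polygon
  # bounding-box prefilter keeps rare-cell gating on millions of points cheap
  tol <- 1e-9 * max(1, max(abs(poly)))
  inbox <- pts[, 1] >= min(poly[, 1]) - tol & pts[, 1] <= max(poly[, 1]) + tol &
           pts[, 2] >= min(poly[, 2]) - tol & pts[, 2] <= max(poly[, 2]) + tol
  if (any(inbox)) {
    bnd <- rbind(poly, poly[1, , drop = FALSE])
    sub <- pts[inbox, , drop = FALSE]
    ins <- mgcv::in.out(bnd, sub)
    # boundary points: in.out is exclusive, the convention here is inclusive
    chk <- which(!ins)
    if (length(chk)) ins[chk] <- .on_boundary(sub[chk, , drop = FALSE], poly, tol)
    inside[inbox] <- ins
  }
  list(inside = inside, count = sum(inside))
}

# distance of points to polygon edges below tolerance?
.on_boundary <- function(pts, poly, tol) {
  out <- logical(nrow(pts))
  n <- nrow(poly)
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[(e %% n) + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    out <- out | d2 <= tol^2
    if (all(out)) break
  }
  out
}

#' Rare-cell abundance with exact binomial confidence interval
#'
#' Estimates the abundance ratio of a gated subpopulation with a
#' Clopper-Pearson interval. When the gate was drawn at a density level that
#' captures only part of the target population (e.g. a 50 %-of-max contour),
#' supply its measured `gate_efficiency` (stored in the gate provenance by
#' [derive_gate()]) to rescale the estimate to the full population.
#'
#' @param gated_count cells inside the gate.
#' @param total_count total cells analysed (> 0).
#' @param conf_level confidence level (default 0.95).
#' @param gate_efficiency fraction of the target population the gate captures
#'   (default 1 = report the raw gated fraction).
#' @return List with `ratio`, `ci` (length-2), `gated`, `total`,
#'   `gate_efficiency`.
#' @export
rare_cell_ratio <- function(gated_count, total_count, conf_level = 0.95,
                            gate_efficiency = 1) {
  stopifnot(total_count > 0, gate_efficiency > 0, gate_efficiency <= 1)
  if (gated_count > total_count) stop("gated count exceeds total count")
  ci <- if (gated_count == 0 && total_count > 0) {
    c(0, 1 - (1 - conf_level / 2)^(1 / total_count))  # binom.test handles this too
  } else NULL
  bt <- binom.test(gated_count, total_count, conf.level = conf_level)
  ci <- as.numeric(bt$conf.int)
  list(ratio = gated_count / total_count / gate_efficiency,
       ci = pmin(ci / gate_efficiency, 1),
       gated = gated_count, total = total_count,
       gate_efficiency = gate_efficiency)
}

#' Write / read a gate as JSON
#' @param gate a `gate_region`.
#' @param path JSON path.
#' @export
write_gate <- function(gate, path) {
  obj <- list(schema = "vdcyto_gate_v1", level = gate$level,
              provenance = gate$provenance,
              polygon = unname(as.data.frame(gate$polygon)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "vdcyto_gate_v1")) stop("not a vdcyto gate file")
  gate_region(as.matrix(obj$polygon), obj$level, obj$provenance)
}
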