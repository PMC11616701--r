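# Population specifications and record-level sampling of synthetic truths.

#' Describe a synthetic cell population
#'
#' Groups the distributional parameters used to emulate one cell population:
#' deformability and projected-area distributions (normal, truncated to the
#' physically admissible ranges), transit velocity, and the bright-field
#' intensity contrast used when rendering.
#'
#' @param name population label.
#' @param mean_D,sd_D mean and SD of deformability; `mean_D` must lie in
#'   `[0, 0.5]`. Sampled values are truncated to `[0, min(0.5, family max))`.
#' @param mean_area_um2,sd_area_um2 mean and SD of projected area (um^2);
#'   sampled areas are truncated to be positive.
#' @param mean_velocity_mps mean transit velocity (m/s).
#' @param intensity_contrast interior darkening as a fraction of the background
#'   level (0 = invisible, 1 = black).
#' @return A `population_spec` object.
#' @export
population_spec <- function(name, mean_D, sd_D, mean_area_um2, sd_area_um2,
                            mean_velocity_mps = 0.7, intensity_contrast = 0.85) {
  stopifnot(mean_D >= 0, mean_D <= 0.5, sd_D >= 0,
            mean_area_um2 > 0, sd_area_um2 >= 0,
            mean_velocity_mps >= 0,
            intensity_contrast > 0, intensity_contrast <= 1)
  structure(list(name = name, mean_D = mean_D, sd_D = sd_D,
                 mean_area_um2 = mean_area_um2, sd_area_um2 = sd_area_um2,
                 mean_velocity_mps = mean_velocity_mps,
                 intensity_contrast = intensity_contrast),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("population_spec '%s': D ~ N(%.3f, %.3f), area ~ N(%.1f, %.1f) um^2, v = %.2f m/s\n",
              x$name, x$mean_D, x$sd_D, x$mean_area_um2, x$sd_area_um2,
              x$mean_velocity_mps))
  invisible(x)
}

# inverse-CDF sampling from N(mu, sd) truncated to [lo, hi]; deterministic
# given the RNG stream. Returns values and the analytic mean shift (bias).
.rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (sd == 0) {
    val <- rep(min(max(mu, lo), hi), n)
    return(list(values = val, bias = val[1] - mu))
  }
  a <- pnorm(lo, mu, sd); b <- pnorm(hi, mu, sd)
  u <- runif(n, a, b)
  val <- qnorm(u, mu, sd)
  # analytic truncated-normal mean
  za <- (lo - mu) / sd; zb <- (hi - mu) / sd
  tmean <- mu + sd * (dnorm(za) - dnorm(zb)) / (b - a)
  list(values = pmin(pmax(val, lo), hi), bias = tmean - mu)
}

#' Sample synthetic cell truths from a population specification
#'
#' Draws per-cell true deformability and area from truncated normal
#' distributions, solves the bullet family for each deformability, and scales
#' the base radius so the polygon area matches the sampled area exactly. The
#' returned records carry the exact geometric ground truth of every cell.
#'
#' @param spec a [population_spec()].
#' @param n number of cells (>= 1).
#' @param seed integer seed; fixed seed fully determines the output.
#' @param polygons if `TRUE`, attach the list of truth polygons (micrometre
#'   coordinates, shape-origin centred) as attribute `"polygons"`. Off by
#'   default to keep large record-level samples light.
#' @return Data frame of class `synthetic_truth` with columns `population`,
#'   `p`, `base_radius_um`, `area_true`, `perimeter_true`,
#'   `deformability_true`, `velocity`, `intensity_contrast`, and the
#'   truncation-bias record in attributes `truncation_bias_D` /
#'   `truncation_bias_area`. If the documented truncation bias exceeds 10 % of
#'   the corresponding mean, a warning is issued and recorded in attribute
#'   `"warnings"`.
#' @export
sample_population <- function(spec, n, seed = NULL, polygons = FALSE) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d_hi <- min(0.5, max_bullet_deformability() * 0.999)
  ds <- .rtruncnorm(n, spec$mean_D, spec$sd_D, 0, d_hi)
  ar <- .rtruncnorm(n, spec$mean_area_um2, spec$sd_area_um2,
                    max(1e-3, 0.02 * spec$mean_area_um2), Inf)
  tab <- .family_table()
  p <- approx(tab$D, tab$p, xout = ds$values, rule = 2)$y
  unit_area <- .family_at(p, "area")
  r0 <- sqrt(ar$values / unit_area)
  out <- data.frame(
    population = spec$name,
    p = p,
    base_radius_um = r0,
    area_true = ar$values,
    perimeter_true = .family_at(p, "perimeter") * r0,
    deformability_true = .family_at(p, "D"),
    velocity = spec$mean_velocity_mps,
    intensity_contrast = spec$intensity_contrast,
    stringsAsFactors = FALSE)
  warn <- character(0)
  if (spec$mean_D > 0 && abs(ds$bias) > 0.1 * spec$mean_D) {
    warn <- c(warn, sprintf("deformability truncation bias %.4f exceeds 10%% of mean_D", ds$bias))
  }
  if (abs(ar$bias) > 0.1 * spec$mean_area_um2) {
    warn <- c(warn, sprintf("area truncation bias %.2f exceeds 10%% of mean area", ar$bias))
  }
  for (w in warn) warning(w, call. = FALSE)
  attr(out, "truncation_bias_D") <- ds$bias
  attr(out, "truncation_bias_area") <- ar$bias
  attr(out, "warnings") <- warn
  if (polygons) {
    attr(out, "polygons") <- lapply(seq_len(n), function(i) {
      bullet_polygon(bullet_shape(p[i], r0[i]))
    })
  }
  class(out) <- c("synthetic_truth", "data.frame")
  out
}

#' Reconstruct the exact polygon of one synthetic truth record
#'
#' @param truth a `synthetic_truth` data frame.
#' @param i row index.
#' @param n_vertices polygon resolution.
#' @return Two-column matrix of vertices in micrometres. If the record has
#'   placement columns (`x_um`, `y_um` from [simulate_stream()]), the polygon
#'   is translated to its frame position.
#' @export
truth_polygon <- function(truth, i, n_vertices = 1024L) {
  poly <- bullet_polygon(bullet_shape(truth$p[i], truth$base_radius_um[i]),
                         n_vertices)
  if (all(c("x_um", "y_um") %in% names(truth))) {
    poly[, 1] <- poly[, 1] + truth$x_um[i]
    poly[, 2] <- poly[, 2] + truth$y_um[i]
  }
  poly
}
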