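# Scatter / density figures: deformability versus cell size with
# 50%-of-max density contours, in the style used for population phenotyping.

#' Plot deformability versus cell size with density contours
#'
#' Draws the per-cell scatter coloured by local density, overlays iso-density
#' contours (50 % of maximum by default), and optionally one or more gates.
#'
#' @param records `results_table` or two-column (area, deformability) data.
#' @param method density method for the contour overlay.
#' @param level contour level as a fraction of maximum density.
#' @param gates optional list of `gate_region`s to overlay.
#' @param file optional output path (`.png`); plots to the active device when
#'   `NULL`.
#' @param main plot title.
#' @return The `density_grid` used, invisibly.
#' @export
plot_density <- function(records, method = "kde", level = 0.5, gates = NULL,
                         file = NULL, main = "deformability vs cell size") {
  pts <- .as_points(records)
  grid <- density_map(pts, method = method)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  # colour points by local density (linear scale)
  fx <- findInterval(pts[, 1], grid$x, all.inside = TRUE)
  fy <- findInterval(pts[, 2], grid$y, all.inside = TRUE)
  dens <- grid$z[cbind(fx, fy)]
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[pmax(1, ceiling(64 * dens / max(dens)))]
  plot(pts[, 1], pts[, 2], pch = 16, cex = 0.3, col = col,
       xlab = expression(paste("cell area (", mu, m^2, ")")),
       ylab = "deformability", main = main)
  contour(grid$x, grid$y, grid$z, levels = level * max(grid$z),
          add = TRUE, drawlabels = FALSE, lwd = 2, col = "white")
  if (!is.null(gates)) {
    if (inherits(gates, "gate_region")) gates <- list(gates)
    for (g in gates) {
      polygon(g$polygon[, 1], g$polygon[, 2], border = "red", lwd = 2)
    }
  }
  invisible(grid)
}
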