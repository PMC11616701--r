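# Density maps, half-maximum contours, gating, rare-cell quantification.

test_that("the density mode lands on the distribution mean", {
  set.seed(1)
  pts <- cbind(rnorm(1e5, 100, 8), rnorm(1e5, 0.1, 0.015))
  # smooth KDE surface: argmax is stable at fine resolution; the raw
  # histogram argmax needs enough counts per bin, hence coarser bins
  # grids at the 64-bin working resolution: the statistical error of a mode
  # estimate does not shrink with grid refinement, so "within 2 bins" is a
  # statement about this granularity
  for (setup in list(list("kde", 64, 2), list("histogram", 16, 2.5))) {
    # histogram bound carries half a bin of slack: the true mean can sit on
    # a bin edge, in which case both adjacent bins are equally likely modes
    g <- density_map(pts, method = setup[[1]], bins = setup[[2]])
    idx <- which(g$z == max(g$z), arr.ind = TRUE)[1, ]
    dx <- mean(diff(g$x)); dy <- mean(diff(g$y))
    expect_lt(abs(g$x[idx[1]] - 100), setup[[3]] * dx)
    expect_lt(abs(g$y[idx[2]] - 0.1), setup[[3]] * dy)
  }
})

test_that("identical points occupy a single histogram bin", {
  pts <- cbind(rep(50, 25), rep(0.2, 25))
  g <- density_map(pts, method = "histogram")
  expect_equal(sum(g$z > 0), 1L)
})

test_that("a zero-variance axis is an error for the KDE, naming the axis", {
  pts <- cbind(rep(50, 25), seq(0.1, 0.3, length.out = 25))
  expect_error(density_map(pts, method = "kde"), "area")
  pts2 <- cbind(seq(40, 60, length.out = 25), rep(0.2, 25))
  expect_error(density_map(pts2, method = "kde"), "deformability")
})

test_that("uniform points flatten out as n grows", {
  set.seed(2)
  pts <- cbind(runif(1e6, 0, 100), runif(1e6, 0, 0.3))
  g <- density_map(pts, method = "histogram", bins = 24,
                   range = list(x = c(0, 100), y = c(0, 0.3)))
  expect_lt(max(g$z) / min(g$z), 1.2)
})

test_that("normalised densities integrate to one", {
  set.seed(3)
  pts <- cbind(rnorm(2000, 100, 8), rnorm(2000, 0.1, 0.015))
  expect_lt(abs(density_integral(density_map(pts, "histogram")) - 1), 1e-6)
  expect_lt(abs(density_integral(density_map(pts, "kde")) - 1), 1e-3)
})

test_that("the half-max contour of a Gaussian is the analytic ellipse", {
  set.seed(4)
  n <- 1e5
  sdx <- 8; sdy <- 0.015
  pts <- cbind(rnorm(n, 100, sdx), rnorm(n, 0.1, sdy))
  g <- density_map(pts, method = "kde", bins = 64)
  gates <- half_max_contour(g, 0.5)
  expect_length(gates, 1L)
  P <- gates[[1]]$polygon
  # KDE smoothing widens the Gaussian: sd' = sqrt(sd^2 + h^2)
  h <- g$params$bandwidth
  rx <- sqrt(sdx^2 + h[1]^2) * sqrt(2 * log(2))
  ry <- sqrt(sdy^2 + h[2]^2) * sqrt(2 * log(2))
  # normalised radius of every contour vertex ~ 1 within 2 grid cells
  rn <- sqrt(((P[, 1] - 100) / rx)^2 + ((P[, 2] - 0.1) / ry)^2)
  cell <- 2 * max(mean(diff(g$x)) / rx, mean(diff(g$y)) / ry)
  expect_true(all(abs(rn - 1) < cell))
})

test_that("two well-separated modes yield two contours", {
  set.seed(5)
  pts <- rbind(cbind(rnorm(5e3, 50, 3), rnorm(5e3, 0.05, 0.005)),
               cbind(rnorm(5e3, 150, 3), rnorm(5e3, 0.25, 0.005)))
  g <- density_map(pts, method = "kde", bins = 96)
  gates <- half_max_contour(g, 0.5)
  expect_equal(length(gates), 2L)
})

test_that("level one degenerates to the mode", {
  set.seed(6)
  pts <- cbind(rnorm(5000, 100, 8), rnorm(5000, 0.1, 0.015))
  g <- density_map(pts, method = "kde")
  gates <- half_max_contour(g, 1)
  cell_area <- mean(diff(g$x)) * mean(diff(g$y))
  expect_lt(polygon_area(gates[[1]]$polygon), cell_area)
  expect_error(half_max_contour(g, 0), "level")
  expect_error(half_max_contour(g, 1.2), "level")
})

test_that("derive_gate encloses a plausible share of its reference", {
  set.seed(7)
  ref <- cbind(rnorm(5000, 160, 15), rnorm(5000, 0.1, 0.015))
  gate <- derive_gate(ref)
  inside <- apply_gate(ref, gate)
  expect_gte(inside$count / nrow(ref), 0.40)
  expect_equal(gate$provenance$gate_efficiency, inside$count / nrow(ref))
  # determinism
  gate2 <- derive_gate(ref)
  expect_identical(gate$polygon, gate2$polygon)
})

test_that("tiny references are refused", {
  ref <- cbind(rnorm(10, 100, 5), rnorm(10, 0.1, 0.01))
  expect_error(derive_gate(ref), "below minimum")
  expect_error(derive_gate(ref[0, , drop = FALSE]), "empty")
})

test_that("point-in-gate follows the boundary-inclusive convention", {
  gate <- gate_region(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  res <- apply_gate(cbind(c(0.5, 0.5, 2, 0, 1), c(0.5, 0, 2, 0, 0.5)), gate)
  expect_identical(res$inside, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(res$count, 4L)
})

test_that("gating is invariant to point order and consistent rescaling", {
  set.seed(8)
  pts <- cbind(rnorm(2000, 100, 10), rnorm(2000, 0.1, 0.02))
  gate <- derive_gate(cbind(rnorm(500, 100, 10), rnorm(500, 0.1, 0.02)),
                      min_points = 100)
  r1 <- apply_gate(pts, gate)
  perm <- sample(nrow(pts))
  r2 <- apply_gate(pts[perm, ], gate)
  expect_identical(r1$inside[perm], r2$inside)
  # affine-consistent rescale of both points and gate
  A <- c(3, 40); b <- c(7, 0.5)
  pts2 <- cbind(pts[, 1] * A[1] + b[1], pts[, 2] * A[2] + b[2])
  gate2 <- gate_region(cbind(gate$polygon[, 1] * A[1] + b[1],
                             gate$polygon[, 2] * A[2] + b[2]))
  r3 <- apply_gate(pts2, gate2)
  expect_identical(r1$inside, r3$inside)
})

test_that("rare-cell ratios carry Clopper-Pearson intervals", {
  r <- rare_cell_ratio(100, 1e6)
  expect_equal(r$ratio, 1e-4)
  expect_equal(r$ci[1], 8.136e-05, tolerance = 1e-3)
  expect_equal(r$ci[2], 1.216e-04, tolerance = 1e-3)
  r0 <- rare_cell_ratio(0, 1000)
  expect_equal(r0$ratio, 0)
  expect_equal(r0$ci[1], 0)
  r1 <- rare_cell_ratio(50, 50)
  expect_equal(r1$ratio, 1)
  expect_error(rare_cell_ratio(10, 5), "exceeds")
})

test_that("gates round-trip through JSON", {
  set.seed(9)
  gate <- derive_gate(cbind(rnorm(500, 100, 10), rnorm(500, 0.1, 0.02)),
                      min_points = 100)
  path <- tempfile(fileext = ".json")
  write_gate(gate, path)
  back <- read_gate(path)
  expect_equal(unname(back$polygon), unname(gate$polygon), tolerance = 1e-12)
  expect_equal(back$provenance$gate_efficiency,
               gate$provenance$gate_efficiency)
})
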