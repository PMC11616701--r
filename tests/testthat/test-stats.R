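# Statistical comparisons and summaries.

test_that("the textbook two-by-two case matches enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("identical samples are not significant", {
  x <- rep(c(1, 2, 3, 4, 5), 4)
  res <- mann_whitney_u(x, x)
  expect_gt(res$p_value, 0.9)
  expect_identical(res$stars, "ns")
})

test_that("exact Mann-Whitney equals brute-force enumeration for n <= 6", {
  set.seed(10)
  for (rep in 1:40) {
    nx <- sample(1:6, 1); ny <- sample(1:6, 1)
    v <- sample(1000, nx + ny)  # distinct -> no ties
    x <- v[seq_len(nx)]; y <- v[nx + seq_len(ny)]
    bf <- mwu_exact_bruteforce(x, y)
    res <- mann_whitney_u(x, y)
    expect_equal(unname(res$statistic), bf$U)
    expect_equal(res$p_value, bf$p, tolerance = 1e-12)
  }
})

test_that("well-separated samples are strongly significant", {
  set.seed(11)
  hits <- vapply(1:100, function(i) {
    x <- rnorm(50); y <- rnorm(50, 2)  # shift = 2 sigma
    mann_whitney_u(x, y)$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("empty samples are refused", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("ANOVA matches a manual sum-of-squares computation", {
  g <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
            c = c(13, 9, 11, 8, 7, 12))
  # manual oracle
  all <- unlist(g)
  gm <- mean(all)
  ssb <- sum(lengths(g) * (vapply(g, mean, 1) - gm)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  dfb <- length(g) - 1; dfw <- length(all) - length(g)
  f_manual <- (ssb / dfb) / (ssw / dfw)
  p_manual <- pf(f_manual, dfb, dfw, lower.tail = FALSE)
  res <- one_way_anova(g)
  expect_equal(unname(res$statistic), f_manual, tolerance = 1e-6)
  expect_equal(res$p_value, p_manual, tolerance = 1e-6)
})

test_that("identical constant groups give F = 0 and P = 1", {
  res <- one_way_anova(list(a = c(5, 5, 5), b = c(5, 5, 5), c = c(5, 5, 5)))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(12)
  x <- rnorm(20, 1); y <- rnorm(25, 1.4)
  tt <- t.test(x, y, var.equal = TRUE)
  res <- one_way_anova(list(x = x, y = y))
  expect_equal(unname(res$statistic), unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey on two groups reduces to the unadjusted comparison", {
  set.seed(13)
  g <- list(x = rnorm(15), y = rnorm(15, 1))
  tk <- tukey_hsd(g)
  expect_equal(nrow(tk), 1L)
  expect_equal(tk$p_adjusted, one_way_anova(g)$p_value, tolerance = 1e-8)
})

test_that("Tukey orders pairwise significance sensibly", {
  set.seed(14)
  g <- list(a = rnorm(20), b = rnorm(20, 0.2), c = rnorm(20, 3))
  tk <- tukey_hsd(g)
  expect_equal(nrow(tk), 3L)
  p <- setNames(tk$p_adjusted, tk$comparison)
  expect_gt(p[["b-a"]], 0.05)
  expect_lt(p[["c-a"]], 1e-4)
})

test_that("group preconditions are enforced", {
  expect_error(one_way_anova(list(a = 1:3)), "2 groups")
  expect_error(one_way_anova(list(a = 1:3, b = 5)), "at least 2 observations")
})

test_that("star codes use the strict threshold convention", {
  expect_identical(star_code(c(0.5, 0.033, 0.0329, 0.0021, 0.002,
                               0.0002, 0.00019, 0.0001, 0.00009)),
                   c("ns", "ns", "*", "*", "**", "**", "***", "***", "****"))
})

test_that("summaries support pooled and replicate-mean modes", {
  df <- data.frame(
    deformability = c(1, 2, 3, 0.07, 0.08, 0.09),
    area_um2 = c(10, 20, 30, 100, 100, 100),
    group = rep(c("g1", "g2"), each = 3),
    rep_id = c(1, 1, 1, 1, 2, 3))
  s <- summarize_populations(df, "group")
  g1 <- s[s$group == "g1", ]
  expect_equal(g1$mean_deformability, 2)
  expect_equal(g1$sd_deformability, 1)
  expect_identical(g1$mode, "pooled")
  # replicate means: three replicates with means 0.07/0.08/0.09 -> bar 0.08
  s2 <- summarize_populations(df, "group", replicate = "rep_id")
  g2 <- s2[s2$group == "g2", ]
  expect_equal(g2$mean_deformability, 0.08)
  expect_identical(g2$mode, "replicate_mean")
  expect_equal(g2$n_replicates, 3L)
})

test_that("a zero-deformability group flags its undefined ratio", {
  df <- data.frame(deformability = c(0, 0), area_um2 = c(10, 12),
                   group = "z")
  s <- summarize_populations(df, "group")
  expect_true(is.na(s$size_to_deformability))
  expect_error(summarize_populations(df, "missing_column"), "unknown group")
})
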