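# Population summaries and the statistical comparisons used for mechanical
# phenotyping: Mann-Whitney U, one-way ANOVA with Tukey's HSD, and the
# significance-star convention.

#' Significance stars for a P value
#'
#' Strict thresholds: `P < 0.033` gives `"*"`, `P < 0.0021` `"**"`,
#' `P < 0.0002` `"***"`, `P < 0.0001` `"****"`; otherwise `"ns"`.
#'
#' @param p P value(s) in `[0, 1]`.
#' @return Character vector of star codes.
#' @export
star_code <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.033] <- "*"
  out[p < 0.0021] <- "**"
  out[p < 0.0002] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

.test_result <- function(test, statistic, p, groups) {
  structure(list(test = test, statistic = statistic, p_value = p,
                 groups = groups, stars = star_code(p)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, P = %.4g (%s)\n",
              x$test, paste(x$groups, collapse = " vs "),
              x$statistic, x$p_value, x$stars))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' The U statistic is computed from midrank sums. The two-tailed P value uses
#' the exact permutation distribution when both samples are small
#' (`min(n) <= 8`) and tie-free, and the normal approximation with tie and
#' continuity corrections otherwise.
#'
#' @param x,y numeric samples (each non-empty).
#' @param labels group labels for reporting.
#' @return A `test_result` with the U statistic of `x`.
#' @export
mann_whitney_u <- function(x, y, labels = c("x", "y")) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  r <- rank(c(x, y))  # midranks
  nx <- length(x); ny <- length(y)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(nx, ny) <= 8 && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
  .test_result("Mann-Whitney U", U, min(p, 1), labels)
}

.as_groups <- function(groups, values = NULL, group = NULL) {
  if (!is.null(values)) return(split(values, group))
  stopifnot(is.list(groups))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way analysis of variance
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `test_result` with the F statistic and its P value; degrees of
#'   freedom in attribute `"df"`.
#' @export
one_way_anova <- function(groups) {
  groups <- .as_groups(groups)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (stats::var(values) == 0) {
    # identical constants: no between-group spread at all
    res <- .test_result("one-way ANOVA", 0, 1, names(groups))
    attr(res, "df") <- c(length(groups) - 1L, length(values) - length(groups))
    return(res)
  }
  fit <- aov(values ~ g)
  sm <- summary(fit)[[1]]
  res <- .test_result("one-way ANOVA", sm[["F value"]][1], sm[["Pr(>F)"]][1],
                      names(groups))
  attr(res, "df") <- sm[["Df"]]
  attr(res, "fit") <- fit
  res
}

#' Tukey's HSD multiple comparison
#'
#' Pairwise comparisons after a one-way ANOVA; adjusted P values from the
#' studentized-range distribution with Tukey-Kramer standard errors for
#' unequal group sizes.
#'
#' @inheritParams one_way_anova
#' @return Data frame with one row per pair: `comparison`, `diff`,
#'   `p_adjusted`, `stars`.
#' @export
tukey_hsd <- function(groups) {
  groups <- .as_groups(groups)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  tk <- TukeyHSD(aov(values ~ g))$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             p_adjusted = tk[, "p adj"], stars = star_code(tk[, "p adj"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group population summaries
#'
#' Mean, SD and n of deformability, area, and the size-to-deformability
#' ratio for each group. With a replicate column, summaries are computed per
#' replicate first and then averaged (a bar then represents the mean of
#' replicate means, the convention used in dose-response figures); without
#' one, raw pooled statistics are reported. The mode used is stamped in the
#' output.
#'
#' @param records a `results_table` (or any data frame with `deformability`
#'   and `area_um2`); only accepted rows are summarised when present.
#' @param group name of the grouping column, or a vector of group labels.
#' @param replicate optional replicate-ID column name or vector.
#' @return Data frame with one row per group: `group`, `n`,
#'   `mean_deformability`, `sd_deformability`, `mean_area_um2`,
#'   `sd_area_um2`, `size_to_deformability`, `n_replicates`, `mode`.
#'   The ratio is `NA` (flagged) for groups with mean deformability 0.
#' @export
summarize_populations <- function(records, group, replicate = NULL) {
  df <- as.data.frame(records)
  if ("accepted" %in% names(df)) df <- df[df$accepted, , drop = FALSE]
  gv <- if (length(group) == 1 && is.character(group)) {
    if (!group %in% names(df)) stop("unknown group column: ", group)
    df[[group]]
  } else group
  rv <- if (is.null(replicate)) NULL else if (length(replicate) == 1 && is.character(replicate)) {
    if (!replicate %in% names(df)) stop("unknown replicate column: ", replicate)
    df[[replicate]]
  } else replicate
  one_group <- function(sub, subr) {
    stat <- function(d) c(mD = mean(d$deformability), mA = mean(d$area_um2),
                          sD = sd(d$deformability), sA = sd(d$area_um2))
    if (is.null(subr) || length(unique(subr)) < 2) {
      s <- stat(sub)
      nrep <- 1L; mode <- "pooled"
    } else {
      per <- vapply(split(sub, subr), stat, numeric(4))
      s <- c(mD = mean(per["mD", ]), mA = mean(per["mA", ]),
             sD = sd(per["mD", ]), sA = sd(per["mA", ]))
      nrep <- ncol(per); mode <- "replicate_mean"
    }
    ratio <- if (s[["mD"]] > 0) s[["mA"]] / s[["mD"]] else NA_real_
    data.frame(n = nrow(sub), mean_deformability = s[["mD"]],
               sd_deformability = s[["sD"]], mean_area_um2 = s[["mA"]],
               sd_area_um2 = s[["sA"]], size_to_deformability = ratio,
               n_replicates = nrep, mode = mode, stringsAsFactors = FALSE)
  }
  parts <- lapply(split(seq_len(nrow(df)), gv), function(ii) {
    one_group(df[ii, , drop = FALSE], if (is.null(rv)) NULL else rv[ii])
  })
  out <- do.call(rbind, parts)
  out <- cbind(data.frame(group = names(parts), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
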