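# Nonparametric group comparison of per-block features: Mann-Whitney U,
# bootstrap difference of medians, standard error of the median, and
# notched-box statistics.

#' Mann-Whitney U test
#'
#' U is reported for the first sample: the number of pairs with `x > y` plus
#' half the tied pairs, so `U(x, y) + U(y, x) = n * m`. The two-sided p-value
#' is exact (full null distribution of U) when `n * m <= 400` and there are
#' no ties, otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. With all observations tied the variance is
#' zero and p = 1.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `u_statistic`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n`, `m`.
#' @export
mann_whitney_u <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n * m <= 400) {
    p <- 2 * min(stats::pwilcox(u, n, m),
                 1 - stats::pwilcox(u - 1, n, m))
    p <- min(1, p)
    method <- "exact"
  } else {
    nt <- table(c(x, y))
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - n * m / 2
      z <- z - sign(z) * 0.5                     # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "normal_approx"
  }
  list(u_statistic = u, p_value = p, method = method, n = n, m = m)
}

# column medians of a bootstrap resample matrix
boot_medians <- function(x, n_boot) {
  mat <- matrix(sample(x, length(x) * n_boot, replace = TRUE), length(x))
  apply(mat, 2, stats::median)
}

#' Bootstrap difference of medians
#'
#' Resamples the two groups independently with replacement and returns the
#' observed `median(x) - median(y)` with the percentile confidence interval
#' of the bootstrap distribution. Deterministic given the seed.
#'
#' @param x,y numeric vectors.
#' @param n_boot bootstrap replicates (>= 100; default 10000).
#' @param seed integer seed (the caller's RNG state is left untouched).
#' @param conf_level confidence level (default 0.95).
#' @return list with `median_diff`, `ci_low`, `ci_high`.
#' @export
bootstrap_median_diff <- function(x, y, n_boot = 10000L, seed = 1L,
                                  conf_level = 0.95) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  with_seed(seed, {
    d <- boot_medians(x, n_boot) - boot_medians(y, n_boot)
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(d, c(a, 1 - a), type = 7))
    list(median_diff = stats::median(x) - stats::median(y),
         ci_low = ci[1], ci_high = ci[2])
  })
}

#' Bootstrap standard error of the median
#'
#' Standard deviation of the medians of `n_boot` resamples.
#'
#' @inheritParams bootstrap_median_diff
#' @return scalar standard error.
#' @export
median_se <- function(x, n_boot = 10000L, seed = 1L) {
  if (length(x) == 0L) stop("sample must be non-empty")
  with_seed(seed, stats::sd(boot_medians(x, n_boot)))
}

#' Notched-box statistics
#'
#' Median, quartiles (linear-interpolation convention, R quantile type 7) and
#' the notch `median +/- 2 * SE(median)`, the standard error estimated by
#' bootstrap, so the notch width is exactly 4 standard errors.
#'
#' @inheritParams bootstrap_median_diff
#' @return list with `median`, `q1`, `q3`, `notch_low`, `notch_high`,
#'   `se_median`.
#' @export
notched_box_stats <- function(x, n_boot = 10000L, seed = 1L) {
  se <- median_se(x, n_boot = n_boot, seed = seed)
  md <- stats::median(x)
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  list(median = md, q1 = q[1], q3 = q[2],
       notch_low = md - 2 * se, notch_high = md + 2 * se, se_median = se)
}

# default feature set for group comparison: homogeneity is omitted because
# heterogeneity = 1 - homogeneity carries the same test
DEFAULT_COMPARE_FEATURES <- c(
  "patch_count", "mean_patch_area_px", "mean_fg_intensity",
  "mean_intensity_per_patch", "energy", "contrast", "heterogeneity"
)

#' Compare per-block feature distributions between two groups
#'
#' Pools all selected blocks of each group into one sample per feature
#' (optionally aggregating to per-image means first), then runs the
#' Mann-Whitney U test, the bootstrap difference of medians with percentile
#' confidence interval, the bootstrap standard error of the median, and
#' notched-box statistics for every feature. Undefined values (e.g. patch
#' means of blocks with no patches) are dropped per feature, with the
#' effective n reported.
#'
#' @param features data.frame in the feature-table schema (see
#'   [write_feature_table()]).
#' @param group_a,group_b group labels present in `features$group`; the
#'   reported difference is `median(a) - median(b)`.
#' @param feature_names feature columns to compare (default: the seven
#'   standard features).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed (mandatory for reproducibility).
#' @param conf_level bootstrap confidence level.
#' @param pooling `"block"` (every selected block is one observation, the
#'   literal procedure) or `"image"` (per-image means, robust to within-image
#'   correlation).
#' @param correction multiple-testing correction across features: `"none"`
#'   (default), `"bonferroni"` or `"fdr"`.
#' @return object of class `sted_comparison`: list with `results` (one row
#'   per feature), `samples` (the per-group value vectors, for plotting) and
#'   the settings used.
#' @export
compare_groups <- function(features, group_a, group_b,
                           feature_names = DEFAULT_COMPARE_FEATURES,
                           n_boot = 10000L, seed = 1L, conf_level = 0.95,
                           pooling = c("block", "image"),
                           correction = c("none", "bonferroni", "fdr")) {
  pooling <- match.arg(pooling)
  correction <- match.arg(correction)
  for (g in c(group_a, group_b))
    if (!g %in% features$group)
      stop("group '", g, "' not present in the feature table")
  missing <- setdiff(feature_names, names(features))
  if (length(missing))
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  rows <- list(); samples <- list()
  for (i in seq_along(feature_names)) {
    f <- feature_names[i]
    pull <- function(g) {
      sub <- features[features$group == g, ]
      v <- sub[[f]]
      if (pooling == "image")
        v <- as.numeric(tapply(v, sub$image_id,
                               function(z) mean(z, na.rm = TRUE)))
      v <- v[is.finite(v)]
      if (length(v) < 2L)
        stop("group '", g, "' has fewer than 2 defined values for '", f, "'")
      v
    }
    a <- pull(group_a); b <- pull(group_b)
    mw <- mann_whitney_u(a, b)
    bd <- bootstrap_median_diff(a, b, n_boot = n_boot,
                                seed = seed + i, conf_level = conf_level)
    nb_a <- notched_box_stats(a, n_boot = n_boot, seed = seed + i)
    nb_b <- notched_box_stats(b, n_boot = n_boot, seed = seed + i + 1L)
    rows[[f]] <- data.frame(
      feature = f, n_a = length(a), n_b = length(b),
      u_statistic = mw$u_statistic, p_value = mw$p_value,
      median_a = stats::median(a), median_b = stats::median(b),
      median_diff = bd$median_diff, ci_low = bd$ci_low, ci_high = bd$ci_high,
      se_median_a = nb_a$se_median, se_median_b = nb_b$se_median,
      notch_a_low = nb_a$notch_low, notch_a_high = nb_a$notch_high,
      notch_b_low = nb_b$notch_low, notch_b_high = nb_b$notch_high,
      stringsAsFactors = FALSE)
    samples[[f]] <- list(a = a, b = b)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (correction != "none") {
    meth <- if (correction == "bonferroni") "bonferroni" else "BH"
    res$p_adjusted <- stats::p.adjust(res$p_value, method = meth)
  }
  structure(list(results = res, samples = samples,
                 group_a = group_a, group_b = group_b,
                 settings = list(n_boot = n_boot, seed = seed,
                                 conf_level = conf_level, pooling = pooling,
                                 correction = correction)),
            class = "sted_comparison")
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.sted_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s vs %s (%s-level pooling, %d bootstrap replicates)\n\n",
              x$group_a, x$group_b, x$settings$pooling, x$settings$n_boot))
  r <- x$results
  tab <- data.frame(
    feature = r$feature,
    `median a` = signif(r$median_a, 4), `median b` = signif(r$median_b, 4),
    diff = signif(r$median_diff, 4),
    `95% CI` = sprintf("[%.4g, %.4g]", r$ci_low, r$ci_high),
    U = r$u_statistic, p = signif(r$p_value, 3), sig = p_stars(r$p_value),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("\nSignif.: *** p<0.001, ** p<0.01, * p<0.05\n")
  invisible(x)
}

#' @export
summary.sted_comparison <- function(object, ...) object$results

#' @export
as.data.frame.sted_comparison <- function(x, ...) x$results
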