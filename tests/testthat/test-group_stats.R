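# Mann-Whitney U, bootstrap difference of medians, SE of the median,
# notched-box statistics, group comparison

test_that("separated samples give U = 0 and the enumerated exact p", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 2 / 6, tolerance = 1e-12)  # 2 * 1/C(4,2)
  expect_equal(mw$method, "exact")
})

test_that("fully tied samples give U = nm/2 and p = 1", {
  mw <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(mw$u_statistic, 4.5)
  expect_equal(mw$p_value, 1)
})

test_that("U and exact p match full enumeration for small samples", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- round(runif(n, 0, 100), 3); y <- round(runif(m, 20, 120), 3)
    if (anyDuplicated(c(x, y))) next
    mw <- mann_whitney_u(x, y)
    orc <- oracle_mw_enum(x, y)
    expect_equal(mw$u_statistic, orc$u)
    expect_equal(mw$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("U(x,y) + U(y,x) = nm including under ties", {
  set.seed(52)
  for (rep in 1:20) {
    x <- sample(1:6, 9, replace = TRUE); y <- sample(2:8, 11, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$u_statistic +
                   mann_whitney_u(y, x)$u_statistic, 9 * 11)
  }
})

test_that("exact and normal-approximation p agree closely at n = m = 7", {
  set.seed(53)
  diffs <- replicate(40, {
    x <- runif(7); y <- runif(7, 0.2, 1.2)
    exact <- mann_whitney_u(x, y)$p_value
    u <- mann_whitney_u(x, y)$u_statistic
    sigma <- sqrt(7 * 7 * 15 / 12)
    z <- u - 24.5; z <- z - sign(z) * 0.5
    approx <- min(1, 2 * pnorm(-abs(z) / sigma))
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("degenerate bootstrap: constant samples give zero-width results", {
  bd <- bootstrap_median_diff(rep(3, 20), rep(3, 30), n_boot = 200, seed = 1)
  expect_equal(bd$median_diff, 0)
  expect_equal(bd$ci_low, 0)
  expect_equal(bd$ci_high, 0)
  expect_equal(median_se(rep(7, 15), n_boot = 200, seed = 1), 0)
})

test_that("bootstrap results are reproducible bit-for-bit under a fixed seed", {
  x <- rnorm(40); y <- rnorm(35, 0.5)
  a <- bootstrap_median_diff(x, y, n_boot = 500, seed = 99)
  b <- bootstrap_median_diff(x, y, n_boot = 500, seed = 99)
  expect_identical(a, b)
  expect_identical(median_se(x, 500, seed = 4), median_se(x, 500, seed = 4))
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(median_se(x, 200, seed = 5))
  expect_identical(runif(1), before)
})

test_that("CI brackets the observed difference and shrinks with n", {
  set.seed(55)
  x <- rnorm(60, 1); y <- rnorm(60)
  bd <- bootstrap_median_diff(x, y, n_boot = 1000, seed = 2)
  expect_lte(bd$ci_low, bd$median_diff)
  expect_gte(bd$ci_high, bd$median_diff)
  widths <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    small <- bootstrap_median_diff(rnorm(25), rnorm(25), 400, seed = s)
    big <- bootstrap_median_diff(rnorm(400), rnorm(400), 400, seed = s)
    (small$ci_high - small$ci_low) - (big$ci_high - big$ci_low)
  }, numeric(1))
  expect_gt(median(widths), 0)
})

test_that("median SE approaches the asymptotic closed form for normal data", {
  set.seed(56)
  ses <- vapply(1:8, function(s) {
    median_se(rnorm(400), n_boot = 2000, seed = s)
  }, numeric(1))
  asym <- 1.2533 / sqrt(400)                    # 1/(2 f(m) sqrt(n))
  expect_lt(abs(mean(ses) - asym) / asym, 0.15)
})

test_that("notch half-width is exactly twice the bootstrap SE of the median", {
  set.seed(57)
  x <- rexp(80)
  nb <- notched_box_stats(x, n_boot = 500, seed = 3)
  expect_equal(nb$notch_high - nb$notch_low, 4 * nb$se_median)
  se <- median_se(x, n_boot = 500, seed = 3)
  expect_equal(nb$se_median, se)
  cs <- notched_box_stats(rep(2, 10), n_boot = 200, seed = 1)
  expect_equal(c(cs$notch_low, cs$median, cs$notch_high), c(2, 2, 2))
})

test_that("quartiles of 1..100 follow the linear-interpolation convention", {
  nb <- notched_box_stats(1:100, n_boot = 200, seed = 1)
  expect_equal(nb$median, 50.5)
  s <- sort(1:100)                              # order-statistic oracle, type 7
  expect_equal(nb$q1, s[25] + 0.75 * (s[26] - s[25]))
  expect_equal(nb$q3, s[75] + 0.25 * (s[76] - s[75]))
})

make_feature_table <- function(n_per_group, shift = 0, seed = 1) {
  set.seed(seed)
  g <- function(group, delta) {
    data.frame(image_id = paste0(group, "_", rep(1:2, length.out = n_per_group)),
               group = group, block_row = 0L,
               block_col = seq_len(n_per_group) - 1L,
               n_pixels_in_block = 10000L,
               patch_count = rpois(n_per_group, 10 + delta * 5),
               mean_patch_area_px = rlnorm(n_per_group, 3 + delta, 0.3),
               mean_fg_intensity = rnorm(n_per_group, 100 - 10 * delta, 5),
               mean_intensity_per_patch = rnorm(n_per_group, 90 - 10 * delta, 5),
               otsu_threshold = runif(n_per_group, 10, 20),
               energy = plogis(rnorm(n_per_group, -2 - delta, 0.3)),
               contrast = rlnorm(n_per_group, 2 + delta, 0.3),
               homogeneity = plogis(rnorm(n_per_group, 1 - delta, 0.3)),
               heterogeneity = NA, stringsAsFactors = FALSE)
  }
  tab <- rbind(g("control", 0), g("invasive", shift))
  tab$heterogeneity <- 1 - tab$homogeneity
  tab
}

test_that("identical groups give zero median differences and p near 1", {
  tab <- make_feature_table(30, shift = 0, seed = 60)
  tab$group <- rep(c("control", "invasive"), each = 30)
  tab[tab$group == "invasive", 6:14] <- tab[tab$group == "control", 6:14]
  cmp <- compare_groups(tab, "control", "invasive", n_boot = 300, seed = 1)
  expect_true(all(cmp$results$median_diff == 0))
  expect_true(all(cmp$results$p_value > 0.9))
})

test_that("undefined patch means are dropped per feature with n reported", {
  tab <- make_feature_table(20, shift = 1, seed = 61)
  tab$mean_patch_area_px[tab$group == "control"][1:3] <- NA
  cmp <- compare_groups(tab, "control", "invasive", n_boot = 300, seed = 1)
  r <- cmp$results
  expect_equal(r$n_a[r$feature == "mean_patch_area_px"], 17)
  expect_equal(r$n_a[r$feature == "patch_count"], 20)
})

test_that("missing group and missing feature column are rejected by name", {
  tab <- make_feature_table(10, seed = 62)
  expect_error(compare_groups(tab, "control", "metastatic"), "metastatic")
  expect_error(compare_groups(tab[, -7], "control", "invasive"),
               "mean_patch_area_px")
})

test_that("multiple-testing correction and image pooling are applied on request", {
  tab <- make_feature_table(24, shift = 1, seed = 63)
  cmp <- compare_groups(tab, "control", "invasive", n_boot = 300, seed = 1,
                        correction = "bonferroni")
  expect_true(all(cmp$results$p_adjusted >= cmp$results$p_value))
  cmp_img <- compare_groups(tab, "control", "invasive", n_boot = 300, seed = 1,
                            pooling = "image")
  expect_equal(cmp_img$results$n_a[1], 2)       # two image_ids per group
})

test_that("comparison object prints, summarises and plots", {
  tab <- make_feature_table(15, shift = 1, seed = 64)
  cmp <- compare_groups(tab, "control", "invasive", n_boot = 200, seed = 1)
  expect_output(print(cmp), "control vs invasive")
  expect_s3_class(summary(cmp), "data.frame")
  expect_equal(nrow(as.data.frame(cmp)), 7)     # default feature set
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, 900, 700)
  expect_silent(plot(cmp))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})
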