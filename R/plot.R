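#' Notched box plots of a group comparison
#'
#' One panel per feature: boxes span the quartiles, notches span
#' `median +/- 2 * SE(median)` (bootstrap SE, so non-overlapping notches give
#' a visual median-difference test), whiskers extend to the most extreme
#' values within 1.5 IQR, and a thin red line marks the median.
#'
#' @param x a `sted_comparison` from [compare_groups()].
#' @param features subset of features to draw (default: all compared).
#' @param ... ignored.
#' @export
plot.sted_comparison <- function(x, features = x$results$feature, ...) {
  features <- intersect(features, x$results$feature)
  n <- length(features)
  if (n == 0L) stop("no features to plot")
  old <- graphics::par(mfrow = grDevices::n2mfrow(n), mar = c(2.5, 3.5, 2, 0.5),
                       mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (f in features) {
    r <- x$results[x$results$feature == f, ]
    s <- x$samples[[f]]
    draw_notched_pair(s$a, s$b, r, x$group_a, x$group_b, f)
  }
  invisible(x)
}

draw_notched_pair <- function(a, b, r, name_a, name_b, feature) {
  vals <- list(a, b)
  notches <- list(c(r$notch_a_low, r$notch_a_high),
                  c(r$notch_b_low, r$notch_b_high))
  meds <- c(r$median_a, r$median_b)
  ylim <- range(unlist(vals), unlist(notches), finite = TRUE)
  graphics::plot(NA, xlim = c(0.5, 2.5), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = feature,
                 main = paste0(feature, " ", p_stars(r$p_value)))
  graphics::axis(1, at = 1:2, labels = c(name_a, name_b))
  for (i in 1:2) {
    v <- vals[[i]]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7)
    iqr <- q[2] - q[1]
    wl <- min(v[v >= q[1] - 1.5 * iqr]); wh <- max(v[v <= q[2] + 1.5 * iqr])
    hw <- 0.28; nw <- 0.14                       # box and notch half-widths
    nl <- notches[[i]][1]; nh <- notches[[i]][2]
    # box with notch cut at the median
    xx <- c(i - hw, i + hw, i + hw, i + nw, i + hw, i + hw,
            i - hw, i - hw, i - nw, i - hw)
    yy <- c(q[1], q[1], nl, meds[i], nh, q[2], q[2], nh, meds[i], nl)
    graphics::polygon(xx, yy, col = "grey90", border = "black")
    graphics::segments(i - nw, meds[i], i + nw, meds[i], col = "red", lwd = 1.5)
    graphics::segments(i, q[2], i, wh); graphics::segments(i, q[1], i, wl)
    graphics::segments(i - hw / 2, wh, i + hw / 2, wh)
    graphics::segments(i - hw / 2, wl, i + hw / 2, wl)
    out <- v[v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr]
    if (length(out)) graphics::points(rep(i, length(out)), out, cex = 0.6)
  }
}
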