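# Per-block patch analysis: Otsu binarisation, 8-connected component
# labelling, and patch count/size/intensity statistics.

#' Otsu threshold of one grid block
#'
#' Builds a 256-bin histogram spanning the block's min–max range and returns
#' the cut maximising the between-class variance of the binned intensities.
#' Ties are broken towards the lowest threshold so the result is
#' deterministic. Pixels strictly greater than the threshold are foreground.
#' A constant block has no separable classes and is flagged degenerate.
#'
#' @param block_pixels numeric matrix (one grid block).
#' @param n_bins histogram resolution (default 256, the conventional choice).
#' @return list with `threshold` (numeric, `NA` if degenerate) and
#'   `degenerate` (logical).
#' @export
otsu_threshold <- function(block_pixels, n_bins = 256L) {
  v <- as.vector(block_pixels)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(list(threshold = NA_real_, degenerate = TRUE))
  bin <- floor(n_bins * (v - lo) / (hi - lo))
  bin[bin == n_bins] <- n_bins - 1L              # v == hi lands in the top bin
  counts <- tabulate(bin + 1L, nbins = n_bins)
  n <- length(v)
  # cut k separates bins [0, k) from [k, n_bins); between-class variance
  # computed in bin-index space
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * (seq_len(n_bins) - 1))
  w0 <- cum_n[seq_len(n_bins - 1L)] / n
  w1 <- 1 - w0
  mu0 <- cum_s[seq_len(n_bins - 1L)] / pmax(cum_n[seq_len(n_bins - 1L)], 1)
  mu1 <- (cum_s[n_bins] - cum_s[seq_len(n_bins - 1L)]) /
    pmax(n - cum_n[seq_len(n_bins - 1L)], 1)
  bcv <- w0 * w1 * (mu1 - mu0)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bcv)                            # which.max takes the first tie
  list(threshold = lo + k * (hi - lo) / n_bins, degenerate = FALSE)
}

#' Label 8-connected foreground components
#'
#' Components are labelled 1..n in order of first encounter when scanning the
#' block row by row (row-major), background is 0. Connectivity includes
#' diagonal neighbours, so two pixels touching only at a corner belong to the
#' same patch.
#'
#' @param binary_block logical/0-1 matrix.
#' @return list with `labels` (integer matrix) and `patch_count`.
#' @export
label_components <- function(binary_block) {
  m <- unclass(binary_block) != 0
  h <- nrow(m); w <- ncol(m)
  labels <- matrix(0L, h, w)
  fg <- which(m)                                 # column-major linear indices
  n_fg <- length(fg)
  if (n_fg == 0L) return(list(labels = labels, patch_count = 0L))
  id <- integer(h * w)                           # pixel index -> vertex id
  id[fg] <- seq_len(n_fg)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  # four forward directions cover all 8-neighbour pairs once
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ok <- r + d[1] >= 1L & r + d[1] <= h & c + d[2] <= w
    nb <- fg[ok] + d[1] + d[2] * h
    has <- m[nb]
    edges <- c(edges, rbind(id[fg[ok][has]], id[nb[has]]))
  }
  g <- igraph::make_graph(edges, n = n_fg, directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel to row-major first-encounter order
  rm_order <- order((r - 1L) * w + (c - 1L))
  relabel <- integer(max(comp))
  nxt <- 0L
  for (i in rm_order) {
    if (relabel[comp[i]] == 0L) { nxt <- nxt + 1L; relabel[comp[i]] <- nxt }
  }
  labels[fg] <- relabel[comp]
  list(labels = labels, patch_count = nxt)
}

#' Patch statistics of one grid block
#'
#' Binarises the block with [otsu_threshold()], labels 8-connected foreground
#' components, and summarises them. `mean_patch_area_px` is foreground pixels
#' divided by patch count; `mean_fg_intensity` is the mean original intensity
#' over all foreground pixels (the binarised block used as a mask);
#' `mean_intensity_per_patch` is the unweighted mean over patches of each
#' patch's mean intensity — two distinct readouts of cluster intensity. A
#' degenerate (constant) block yields `patch_count` 0 with all means
#' undefined (`NA`).
#'
#' @param block_pixels numeric matrix.
#' @param min_patch_area_px drop components smaller than this (default 1,
#'   i.e. no size filter).
#' @return list of class `patch_stats` with fields `patch_count`,
#'   `mean_patch_area_px`, `mean_fg_intensity`, `mean_intensity_per_patch`,
#'   `otsu_threshold`.
#' @export
patch_statistics <- function(block_pixels, min_patch_area_px = 1L) {
  ot <- otsu_threshold(block_pixels)
  empty <- list(patch_count = 0L, mean_patch_area_px = NA_real_,
                mean_fg_intensity = NA_real_,
                mean_intensity_per_patch = NA_real_,
                otsu_threshold = ot$threshold)
  if (ot$degenerate) return(structure(empty, class = "patch_stats"))
  binary <- block_pixels > ot$threshold
  lab <- label_components(binary)
  if (lab$patch_count == 0L) return(structure(empty, class = "patch_stats"))
  lv <- lab$labels[lab$labels > 0L]
  pv <- block_pixels[lab$labels > 0L]
  areas <- tabulate(lv, nbins = lab$patch_count)
  keep <- which(areas >= min_patch_area_px)
  if (length(keep) == 0L) return(structure(empty, class = "patch_stats"))
  sel <- lv %in% keep
  lv <- lv[sel]; pv <- pv[sel]
  patch_means <- tapply(pv, lv, mean)
  structure(list(
    patch_count = length(keep),
    mean_patch_area_px = length(lv) / length(keep),
    mean_fg_intensity = mean(pv),
    mean_intensity_per_patch = mean(patch_means),
    otsu_threshold = ot$threshold
  ), class = "patch_stats")
}

#' @export
print.patch_stats <- function(x, ...) {
  cat(sprintf("<patch_stats> %d patch(es)", x$patch_count))
  if (x$patch_count > 0)
    cat(sprintf(", mean area %.2f px, fg intensity %.2f, per-patch %.2f",
                x$mean_patch_area_px, x$mean_fg_intensity,
                x$mean_intensity_per_patch))
  cat("\n")
  invisible(x)
}
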