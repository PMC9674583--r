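# Gray-level co-occurrence texture: quantisation, GLCMs at the twelve
# spatial offsets (4 distances x 3 angles), Haralick energy / contrast /
# homogeneity per GLCM, and the rotation/offset-invariant reduction of each
# 4x3 feature matrix via its leading singular value.

#' Default spatial offsets: distances 1..4 at 0, 45 and 90 degrees
#'
#' `[dx, dy]` pairs, dx = column offset, dy = row offset:
#' `[k, 0]` horizontal (0 deg), `[k, k]` diagonal (45 deg), `[0, k]`
#' vertical (90 deg), for k = 1..4. No 135-degree offsets are computed.
#'
#' @return data.frame with columns `dx`, `dy`, `distance`, `angle`.
#' @export
glcm_offsets <- function() {
  k <- 1:4
  rbind(
    data.frame(dx = k, dy = 0L, distance = k, angle = 0),
    data.frame(dx = k, dy = k, distance = k, angle = 45),
    data.frame(dx = 0L, dy = k, distance = k, angle = 90)
  )
}

#' Texture configuration
#'
#' @param levels number of gray levels after quantisation (default 64).
#' @param quantization `"block_minmax"` (bins span each block's own min–max)
#'   or `"global_range"` (bins span `global_range`, e.g. the full 16-bit
#'   scale).
#' @param global_range numeric length-2 range used when
#'   `quantization = "global_range"`.
#' @param symmetric accumulate each pixel pair in both orders (default TRUE;
#'   required for exact 180-degree rotation robustness).
#' @param homogeneity_form `"inverse_diff_moment"` for weights
#'   `1/(1+(i-j)^2)` (Haralick's inverse difference moment, the default) or
#'   `"inverse_diff"` for `1/(1+|i-j|)`.
#' @param offsets data.frame as returned by [glcm_offsets()].
#' @return list of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L,
                        quantization = c("block_minmax", "global_range"),
                        global_range = c(0, 65535),
                        symmetric = TRUE,
                        homogeneity_form = c("inverse_diff_moment",
                                             "inverse_diff"),
                        offsets = glcm_offsets()) {
  quantization <- match.arg(quantization)
  homogeneity_form <- match.arg(homogeneity_form)
  stopifnot(levels >= 2, nrow(offsets) >= 1,
            !any(offsets$dx == 0 & offsets$dy == 0))
  structure(list(levels = as.integer(levels), quantization = quantization,
                 global_range = global_range, symmetric = symmetric,
                 homogeneity_form = homogeneity_form, offsets = offsets),
            class = "glcm_config")
}

#' Quantise a block into discrete gray levels
#'
#' Linear binning: `bin = floor(levels * (v - lo) / (hi - lo))`, clipped to
#' `levels - 1` so the range maximum lands in the top bin. A constant block
#' maps entirely to bin 0.
#'
#' @param block_pixels numeric matrix.
#' @param cfg a [glcm_config()].
#' @return integer matrix with values in `[0, levels)`.
#' @export
quantize_block <- function(block_pixels, cfg = glcm_config()) {
  v <- unclass(block_pixels)
  if (cfg$quantization == "block_minmax") {
    lo <- min(v); hi <- max(v)
  } else {
    lo <- cfg$global_range[1]; hi <- cfg$global_range[2]
    v <- pmin(pmax(v, lo), hi)
  }
  if (hi == lo) {
    q <- matrix(0L, nrow(v), ncol(v))
  } else {
    q <- floor(cfg$levels * (v - lo) / (hi - lo))
    q[q >= cfg$levels] <- cfg$levels - 1L
    storage.mode(q) <- "integer"
  }
  q
}

#' Gray-level co-occurrence matrix at one spatial offset
#'
#' Counts co-occurrences of `(q[r, c], q[r + dy, c + dx])` over all positions
#' where both pixels fall inside the block, optionally symmetrised by adding
#' the transpose, and normalised to sum 1.
#'
#' @param q_block integer matrix from [quantize_block()].
#' @param dx,dy column and row offset of the second pixel.
#' @param levels number of gray levels.
#' @param symmetric symmetrise before normalisation?
#' @return `levels x levels` matrix summing to 1, with attribute `offset`.
#' @export
compute_glcm <- function(q_block, dx, dy, levels, symmetric = TRUE) {
  h <- nrow(q_block); w <- ncol(q_block)
  if (h <= abs(dy) || w <= abs(dx))
    stop("block (", h, "x", w, ") is smaller than the offset span (",
         dx, ",", dy, ")")
  rows <- seq_len(h - abs(dy))
  cols <- seq_len(w - abs(dx))
  if (dy < 0) rows <- rows - dy                  # shift window for negative dy
  if (dx < 0) cols <- cols - dx
  i <- q_block[rows, cols, drop = FALSE]
  j <- q_block[rows + dy, cols + dx, drop = FALSE]
  counts <- tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                     nbins = levels * levels)
  p <- matrix(counts, levels, levels, byrow = TRUE)   # p[i+1, j+1]
  if (symmetric) p <- p + t(p)
  p <- p / sum(p)
  attr(p, "offset") <- c(dx = dx, dy = dy)
  p
}

#' Haralick features of one GLCM
#'
#' Energy is the sum of squared joint probabilities (local gray-level
#' uniformity), contrast weights probabilities by the squared level
#' difference (large local variation), and homogeneity measures concentration
#' near the diagonal.
#'
#' @param g normalised GLCM.
#' @param which one of `"energy"`, `"contrast"`, `"homogeneity"`.
#' @param homogeneity_form see [glcm_config()].
#' @return scalar feature value.
#' @export
haralick_feature <- function(g, which = c("energy", "contrast", "homogeneity"),
                             homogeneity_form = "inverse_diff_moment") {
  which <- match.arg(which)
  L <- nrow(g)
  d <- outer(seq_len(L), seq_len(L), "-")
  switch(which,
    energy = sum(g^2),
    contrast = sum(d^2 * g),
    homogeneity = if (homogeneity_form == "inverse_diff_moment")
      sum(g / (1 + d^2)) else sum(g / (1 + abs(d)))
  )
}

#' Rotation/offset-invariant reduction of a distance-by-angle feature matrix
#'
#' Takes the per-offset values of one Haralick feature arranged as a matrix
#' (rows = distances, columns = angles), and returns its largest singular
#' value scaled by `1/sqrt(rows * cols)`. The scaling makes a constant matrix
#' of value c return c, and singular values are invariant under any
#' permutation of columns (angle relabelling under rotation) or rows.
#'
#' @param feature_matrix numeric matrix, no missing values.
#' @return scalar invariant feature.
#' @export
invariant_form <- function(feature_matrix) {
  m <- as.matrix(feature_matrix)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("undefined feature value at distance row ", bad[1],
         ", angle column ", bad[2])
  }
  svd(m, nu = 0, nv = 0)$d[1] / sqrt(nrow(m) * ncol(m))
}

#' Invariant texture features of one grid block
#'
#' Quantises the block, computes one GLCM per configured offset, evaluates
#' energy, contrast and homogeneity on each, arranges each feature as a
#' distance-by-angle matrix, reduces it with [invariant_form()], and defines
#' heterogeneity as 1 minus the invariant homogeneity.
#'
#' @param block_pixels numeric matrix, at least `(max offset span + 1)` in
#'   each dimension (5x5 for the default offsets).
#' @param cfg a [glcm_config()].
#' @param detail also return the per-offset feature matrices?
#' @return list of class `texture_features` with `energy`, `contrast`,
#'   `homogeneity`, `heterogeneity`; when `detail = TRUE`, also `matrices`
#'   (list of distance-by-angle matrices with angle column names).
#' @export
block_texture <- function(block_pixels, cfg = glcm_config(), detail = FALSE) {
  q <- quantize_block(block_pixels, cfg)
  off <- cfg$offsets
  feats <- c("energy", "contrast", "homogeneity")
  vals <- matrix(NA_real_, nrow(off), 3, dimnames = list(NULL, feats))
  for (k in seq_len(nrow(off))) {
    g <- compute_glcm(q, off$dx[k], off$dy[k], cfg$levels, cfg$symmetric)
    for (f in feats)
      vals[k, f] <- haralick_feature(g, f, cfg$homogeneity_form)
  }
  dists <- sort(unique(off$distance))
  angles <- sort(unique(off$angle))
  mats <- lapply(feats, function(f) {
    m <- matrix(NA_real_, length(dists), length(angles),
                dimnames = list(paste0("d", dists), paste0(angles, "deg")))
    for (k in seq_len(nrow(off)))
      m[match(off$distance[k], dists), match(off$angle[k], angles)] <-
        vals[k, f]
    m
  })
  names(mats) <- feats
  inv <- vapply(mats, invariant_form, numeric(1))
  out <- list(energy = inv[["energy"]], contrast = inv[["contrast"]],
              homogeneity = inv[["homogeneity"]],
              heterogeneity = 1 - inv[["homogeneity"]])
  if (detail) out$matrices <- mats
  structure(out, class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf(
    "<texture_features> energy %.4g, contrast %.4g, homogeneity %.4g, heterogeneity %.4g\n",
    x$energy, x$contrast, x$homogeneity, x$heterogeneity))
  invisible(x)
}
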