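#' Intensity image with physical pixel size
#'
#' A `sted_image` is a plain numeric matrix of non-negative intensities
#' (photon counts or arbitrary deconvolved units) carrying the physical pixel
#' size in nanometres as an attribute. Rows index the vertical axis, columns
#' the horizontal axis, origin at the top-left.
#'
#' @param pixels numeric matrix, all values finite and >= 0.
#' @param pixel_size_nm physical edge length of one pixel in nanometres
#'   (default 25, the sampling used for deconvolved STED frames).
#' @return A `sted_image` object (matrix with a `pixel_size_nm` attribute).
#' @examples
#' img <- sted_image(matrix(0:3, 2, 2), pixel_size_nm = 25)
#' pixel_size(img)
#' @export
sted_image <- function(pixels, pixel_size_nm = 25) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite values")
  if (any(pixels < 0))
    stop("image contains negative intensities")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(pixels, pixel_size_nm = as.numeric(pixel_size_nm),
            class = c("sted_image", class(pixels)))
}

#' @rdname sted_image
#' @param x a `sted_image`.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_nm")
  if (is.null(ps)) stop("object has no pixel_size_nm attribute")
  ps
}

#' @export
print.sted_image <- function(x, ...) {
  cat(sprintf("<sted_image> %d x %d px, %.4g nm/px (%.3g x %.3g um)\n",
              nrow(x), ncol(x), pixel_size(x),
              nrow(x) * pixel_size(x) / 1000, ncol(x) * pixel_size(x) / 1000))
  cat(sprintf("  intensity range [%.6g, %.6g]\n", min(x), max(x)))
  invisible(x)
}

#' Lossless 90-degree rotation
#'
#' Rotates an image counter-clockwise by `k` quarter turns. The pixel multiset
#' is preserved exactly; used to probe the rotation robustness of the texture
#' descriptors.
#'
#' @param image matrix or `sted_image`.
#' @param k number of counter-clockwise quarter turns, one of 1, 2, 3.
#' @return The rotated image, same class and attributes as the input.
#' @export
rotate90 <- function(image, k) {
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || k != as.integer(k) ||
      !(k %in% c(1L, 2L, 3L)))
    stop("`k` must be 1, 2 or 3 (quarter turns)")
  m <- unclass(image)
  ps <- attr(image, "pixel_size_nm")
  for (i in seq_len(k)) {
    # counter-clockwise: result[i, j] = m[j, ncol(m) - i + 1]
    m <- t(m[, rev(seq_len(ncol(m))), drop = FALSE])
  }
  if (inherits(image, "sted_image")) sted_image(m, ps) else m
}

#' Binary region-of-interest mask
#'
#' Validates and normalises a mask to a logical matrix. Any non-zero pixel is
#' foreground.
#'
#' @param pixels logical or numeric matrix.
#' @return logical matrix of class `roi_mask`.
#' @export
roi_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("mask must be a matrix")
  m <- pixels != 0
  if (any(is.na(m))) stop("mask contains missing values")
  if (!any(m)) stop("empty markup: mask has no foreground pixel")
  structure(m, class = c("roi_mask", "matrix", "array"))
}

# run an expression under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}
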