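# Grid segmentation: tile the image into fixed-size blocks from the top-left
# corner and select those overlapping the expert markup region.

#' Tile an image into fixed-size grid blocks
#'
#' The grid starts at the top-left corner of the image. Bounds are 0-based and
#' half-open: block (i, j) covers rows `[r0, r1)` and columns `[c0, c1)`.
#' Truncated remainder blocks at the right/bottom edges are excluded by
#' default because patch and texture statistics depend on block area; set
#' `include_truncated_edge_blocks = TRUE` to keep them.
#'
#' @param image matrix or [sted_image] (only its dimensions are used).
#' @param block_size_px block edge length in pixels (default 100; >= 8).
#' @param include_truncated_edge_blocks keep partial edge blocks?
#' @return data.frame with columns `block_row`, `block_col` (0-based),
#'   `r0`, `r1`, `c0`, `c1` (0-based half-open pixel bounds) and `selected`
#'   (all `NA` until [select_blocks()] is applied), enumerated row-major.
#' @export
build_grid <- function(image, block_size_px = 100L,
                       include_truncated_edge_blocks = FALSE) {
  b <- as.integer(block_size_px)
  if (is.na(b) || b < 8L) stop("block_size_px must be an integer >= 8")
  h <- nrow(image); w <- ncol(image)
  if (h < b || w < b)
    stop("image (", h, "x", w, ") is smaller than one ", b, "-px block")
  n_r <- if (include_truncated_edge_blocks) ceiling(h / b) else h %/% b
  n_c <- if (include_truncated_edge_blocks) ceiling(w / b) else w %/% b
  g <- expand.grid(block_col = seq_len(n_c) - 1L, block_row = seq_len(n_r) - 1L)
  g <- g[, c("block_row", "block_col")]          # row-major enumeration
  g$r0 <- g$block_row * b
  g$r1 <- pmin(g$r0 + b, h)
  g$c0 <- g$block_col * b
  g$c1 <- pmin(g$c0 + b, w)
  g$selected <- NA
  rownames(g) <- NULL
  g
}

#' Select the grid blocks overlapping a region-of-interest mask
#'
#' A block is selected if and only if at least one ROI-foreground pixel lies
#' within its bounds (the "partially or wholly overlapped" rule). Order is
#' preserved.
#'
#' @param grid data.frame from [build_grid()].
#' @param roi logical matrix (`roi_mask`) with the shape of the tiled image.
#' @param image_dim optional `c(rows, cols)` to validate the mask shape
#'   against (the tiled image's dimensions).
#' @return the selected subset of `grid`, with `selected = TRUE`.
#' @export
select_blocks <- function(grid, roi, image_dim = NULL) {
  if (!is.null(image_dim) && !identical(dim(roi), as.integer(image_dim)))
    stop("ROI mask shape ", nrow(roi), "x", ncol(roi),
         " does not match image shape ", image_dim[1], "x", image_dim[2])
  m <- unclass(roi) != 0
  if (max(grid$r1) > nrow(m) || max(grid$c1) > ncol(m))
    stop("ROI mask (", nrow(m), "x", ncol(m), ") is smaller than the grid extent")
  sel <- vapply(seq_len(nrow(grid)), function(i) {
    any(m[(grid$r0[i] + 1L):grid$r1[i], (grid$c0[i] + 1L):grid$c1[i]])
  }, logical(1))
  out <- grid[sel, , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

# extract the pixel submatrix of one grid row
block_pixels <- function(image, block) {
  unclass(image)[(block$r0 + 1L):block$r1, (block$c0 + 1L):block$c1,
                 drop = FALSE]
}
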