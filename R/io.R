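# On-disk contract: 16-bit single-channel TIFF images, 8-bit binary masks
# (TIFF or PNG), feature CSV, labels CSV, comparison reports (CSV + JSON).

MAX_UINT16 <- 65535L

# full feature-table schema, in column order
FEATURE_COLUMNS <- c(
  "image_id", "group", "block_row", "block_col", "n_pixels_in_block",
  "patch_count", "mean_patch_area_px", "mean_fg_intensity",
  "mean_intensity_per_patch", "otsu_threshold",
  "energy", "contrast", "homogeneity", "heterogeneity"
)

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    v <- png::readPNG(path, info = TRUE)
    depth <- attr(v, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    v <- round(v * (2^depth - 1))
  } else {
    stop("unsupported image format '", ext, "' for '", path,
         "' (expected TIFF or PNG)")
  }
  if (length(dim(v)) == 3L)
    stop("'", path, "' has ", dim(v)[3],
         " channels; a single-channel 2-D image is required")
  if (!is.matrix(v)) stop("'", path, "' is not a 2-D image")
  v
}

#' Read a single-channel intensity image
#'
#' Reads a 2-D TIFF (16-bit integer samples are preserved losslessly) or
#' greyscale PNG. Intensities are never rescaled. The physical pixel size is
#' attached from the argument: acquisition metadata embedded in TIFF tags is
#' deliberately ignored because tag conventions vary across microscope
#' software.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_nm pixel edge length in nanometres (default 25).
#' @return a [sted_image].
#' @export
read_intensity_image <- function(path, pixel_size_nm = 25) {
  v <- read_raster(path)
  storage.mode(v) <- "double"
  sted_image(v, pixel_size_nm)
}

#' Write an intensity image as 16-bit TIFF
#'
#' Intensities are rounded to integers and clamped to the 16-bit range, the
#' dialect of real STED exports. Integer-valued images within range round-trip
#' bit-exactly through [read_intensity_image()].
#'
#' @param image matrix or [sted_image].
#' @param path output path (.tif).
#' @export
write_intensity_image <- function(image, path) {
  v <- pmin(pmax(round(unclass(image)), 0), MAX_UINT16)
  ok <- tiff::writeTIFF(v / MAX_UINT16, path, bits.per.sample = 16L,
                        compression = "none")
  if (!isTRUE(ok == 1L) && !isTRUE(ok)) stop("failed to write TIFF '", path, "'")
  invisible(path)
}

#' Read a binary region-of-interest mask
#'
#' Any non-zero pixel is foreground. Values other than 0 and the format
#' maximum trigger a warning (the mask is still binarised). An all-zero mask
#' or a shape mismatch with the paired image is an error.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param expected_dim optional `c(rows, cols)` of the paired image.
#' @return logical matrix of class `roi_mask`.
#' @export
read_roi_mask <- function(path, expected_dim = NULL) {
  v <- read_raster(path)
  if (!is.null(expected_dim) && !identical(dim(v), as.integer(expected_dim)))
    stop("mask '", path, "' has shape ", nrow(v), "x", ncol(v),
         " but the paired image is ", expected_dim[1], "x", expected_dim[2])
  vals <- sort(unique(as.vector(v)))
  if (!all(vals %in% c(0, max(vals))))
    warning("mask '", path, "' is not strictly binary (values: ",
            paste(utils::head(vals, 5), collapse = ", "),
            "...); all non-zero pixels treated as foreground")
  if (!any(v != 0)) stop("empty markup: mask '", path, "' has no foreground pixel")
  roi_mask(v)
}

#' Write a binary mask (8-bit, 0 = outside, 255 = inside)
#'
#' @param mask logical/numeric matrix.
#' @param path output path; format chosen by extension (.png or .tif).
#' @export
write_roi_mask <- function(mask, path) {
  m <- (unclass(mask) != 0) * 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m * (255 / 255), path, bits.per.sample = 8L,
                    compression = "none")
  }
  invisible(path)
}

#' Read / write the per-block feature table
#'
#' One CSV row per selected grid block. Undefined statistics (the patch means
#' of a block with `patch_count` 0, or a degenerate Otsu threshold) are
#' serialised as empty fields and read back as `NA`, which distinguishes
#' "no patches" from "zero area". Numeric values are written with full double
#' precision (15 significant digits).
#'
#' @param records data.frame with the documented feature columns.
#' @param path CSV path.
#' @return `read_feature_table()` returns the data.frame; missing schema
#'   columns are an error naming the column.
#' @export
write_feature_table <- function(records, path) {
  missing <- setdiff(FEATURE_COLUMNS, names(records))
  if (length(missing))
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(records[, FEATURE_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing))
    stop("feature table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a dataset labels table
#'
#' CSV with columns `image_path`, `mask_path`, `group`. Paths are resolved
#' relative to the CSV's directory unless absolute; each must exist.
#'
#' @param path labels CSV.
#' @param require_groups minimum number of distinct groups (2 for comparisons).
#' @return data.frame with absolute `image_path`, `mask_path`, `group`.
#' @export
read_labels <- function(path, require_groups = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "group")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("labels table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$image_path <- resolve(df$image_path)
  df$mask_path <- resolve(df$mask_path)
  for (p in c(df$image_path, df$mask_path))
    if (!file.exists(p)) stop("labels table references missing file '", p, "'")
  if (length(unique(df$group)) < require_groups)
    stop("labels table has ", length(unique(df$group)),
         " group(s); at least ", require_groups, " required")
  df
}
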