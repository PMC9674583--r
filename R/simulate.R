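# Synthetic STED-like image generator: bright sub-diffraction clusters
# (isotropic Gaussian spots) scattered as a homogeneous Poisson process inside
# a lamellipodium-like ROI, over constant background, with optional per-pixel
# Poisson shot noise.

#' Cluster population parameters for the synthetic generator
#'
#' Describes the nanoscale cluster population of one simulated condition.
#' Cluster counts follow a homogeneous spatial Poisson process with density
#' `count_per_block` per 100x100-pixel block area; radii and peak intensities
#' are lognormal with the given means and coefficients of variation (a CV of 0
#' gives a constant).
#'
#' @param count_per_block expected clusters per 100x100-px block area (>= 0;
#'   0 is the degenerate no-signal limit).
#' @param radius_px mean cluster radius in pixels; used as the Gaussian spot
#'   sigma (> 0).
#' @param radius_cv coefficient of variation of the radius (>= 0).
#' @param peak_intensity mean peak photon count per cluster (> 0).
#' @param intensity_cv coefficient of variation of the peak (>= 0).
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(count_per_block = 12, radius_px = 2,
                         radius_cv = 0.25, peak_intensity = 120,
                         intensity_cv = 0.3) {
  stopifnot(count_per_block >= 0, radius_px > 0, radius_cv >= 0,
            peak_intensity > 0, intensity_cv >= 0)
  structure(list(count_per_block = count_per_block, radius_px = radius_px,
                 radius_cv = radius_cv, peak_intensity = peak_intensity,
                 intensity_cv = intensity_cv),
            class = "cluster_spec")
}

#' Full specification of one synthetic image
#'
#' @param image_height_px,image_width_px image dimensions in pixels; each must
#'   be at least twice `min_block_px`.
#' @param pixel_size_nm physical pixel size (default 25 nm, typical of
#'   deconvolved STED sampling).
#' @param background_level mean background photon count (>= 0).
#' @param noise_model `"poisson"` for per-pixel shot noise, `"none"` for the
#'   noiseless rendering.
#' @param roi_shape `"band"` (axis-aligned band along the top edge covering
#'   `band_frac` of the image, a crude lamellipodium stand-in) or `"polygon"`.
#' @param band_frac fraction of image height covered by the band ROI.
#' @param roi_polygon for `roi_shape = "polygon"`: two-column matrix of
#'   (row, col) vertices, 0-based pixel coordinates.
#' @param cluster a [cluster_spec()].
#' @param seed integer; together with the spec it fully determines the output.
#' @param min_block_px grid block size the dimensions are validated against.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_height_px, image_width_px,
                           pixel_size_nm = 25, background_level = 5,
                           noise_model = c("poisson", "none"),
                           roi_shape = c("band", "polygon"),
                           band_frac = 0.3, roi_polygon = NULL,
                           cluster = cluster_spec(), seed = 1L,
                           min_block_px = 100L) {
  noise_model <- match.arg(noise_model)
  roi_shape <- match.arg(roi_shape)
  stopifnot(image_height_px >= 2, image_width_px >= 2,
            pixel_size_nm > 0, background_level >= 0,
            band_frac > 0, band_frac <= 1,
            inherits(cluster, "cluster_spec"), length(seed) == 1L)
  if (image_height_px < min_block_px || image_width_px < min_block_px)
    stop("image dimensions ", image_height_px, "x", image_width_px,
         " are smaller than one ", min_block_px, "-px grid block")
  if (roi_shape == "polygon" && (is.null(roi_polygon) || nrow(roi_polygon) < 3))
    stop("roi_shape = 'polygon' requires a roi_polygon with >= 3 vertices")
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 pixel_size_nm = pixel_size_nm,
                 background_level = background_level,
                 noise_model = noise_model, roi_shape = roi_shape,
                 band_frac = band_frac, roi_polygon = roi_polygon,
                 cluster = cluster, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# lognormal draws with mean m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# even-odd ray-casting point-in-polygon, vectorised over points
points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

make_roi <- function(spec) {
  h <- spec$image_height_px; w <- spec$image_width_px
  if (spec$roi_shape == "band") {
    hb <- max(1L, round(spec$band_frac * h))
    m <- matrix(FALSE, h, w)
    m[seq_len(hb), ] <- TRUE
  } else {
    rr <- matrix(rep(seq_len(h) - 1L, w), h, w)
    cc <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
    m <- matrix(points_in_polygon(as.vector(rr), as.vector(cc),
                                  spec$roi_polygon[, 1], spec$roi_polygon[, 2]),
                h, w)
  }
  roi_mask(m)
}

#' Simulate one STED-like cell image with ground truth
#'
#' Renders `background + sum of isotropic Gaussian spots` (sigma = cluster
#' radius) at a Poisson-distributed number of cluster centres placed uniformly
#' inside the ROI, then applies per-pixel Poisson noise if enabled. Identical
#' spec + seed give bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `image` ([sted_image]), `mask` (`roi_mask`) and
#'   `ground_truth` (list of `centres` — n x 2 matrix of 0-based subpixel
#'   (row, col) coordinates — `radii_px` and `peaks`).
#' @export
simulate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    h <- spec$image_height_px; w <- spec$image_width_px
    mask <- make_roi(spec)
    roi_idx <- which(mask)                       # column-major linear indices
    density <- spec$cluster$count_per_block / (100 * 100)
    n_clust <- stats::rpois(1L, density * length(roi_idx))
    img <- matrix(spec$background_level, h, w)
    if (n_clust > 0) {
      pix <- sample(roi_idx, n_clust, replace = TRUE)
      r0 <- ((pix - 1L) %% h) + stats::runif(n_clust) - 0.5      # 0-based rows
      c0 <- ((pix - 1L) %/% h) + stats::runif(n_clust) - 0.5     # 0-based cols
      radii <- rlnorm_cv(n_clust, spec$cluster$radius_px, spec$cluster$radius_cv)
      peaks <- rlnorm_cv(n_clust, spec$cluster$peak_intensity,
                         spec$cluster$intensity_cv)
      for (i in seq_len(n_clust)) {
        s <- radii[i]
        half <- ceiling(4 * s)
        rows <- max(1L, floor(r0[i] + 1 - half)):min(h, ceiling(r0[i] + 1 + half))
        cols <- max(1L, floor(c0[i] + 1 - half)):min(w, ceiling(c0[i] + 1 + half))
        dr <- (rows - 1) - r0[i]
        dc <- (cols - 1) - c0[i]
        img[rows, cols] <- img[rows, cols] +
          peaks[i] * exp(-outer(dr^2, dc^2, "+") / (2 * s^2))
      }
      gt <- list(centres = cbind(row = r0, col = c0), radii_px = radii,
                 peaks = peaks)
    } else {
      gt <- list(centres = matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("row", "col"))),
                 radii_px = numeric(0), peaks = numeric(0))
    }
    if (spec$noise_model == "poisson")
      img <- matrix(as.numeric(stats::rpois(length(img), img)), h, w)
    list(image = sted_image(img, spec$pixel_size_nm), mask = mask,
         ground_truth = gt)
  })
}

#' Built-in condition presets
#'
#' `preset_spec("control")` is the control-like regime; the invasive-like
#' regime is derived from it by doubling the cluster density, scaling the
#' radius by 1.5 and the peak intensity by 0.7, mirroring the direction of the
#' reported phenotype differences (more clusters, ~50% larger, lower intensity
#' per cluster).
#'
#' @param regime `"control"` or `"invasive"`.
#' @param image_height_px,image_width_px frame size (default 1024x1024, a
#'   typical acquisition frame).
#' @param seed integer seed.
#' @param ... further arguments passed to [synthetic_spec()].
#' @return a [synthetic_spec()].
#' @export
preset_spec <- function(regime = c("control", "invasive"),
                        image_height_px = 1024, image_width_px = 1024,
                        seed = 1L, ...) {
  regime <- match.arg(regime)
  base <- cluster_spec()
  cl <- if (regime == "invasive") {
    cluster_spec(count_per_block = base$count_per_block * 2,
                 radius_px = base$radius_px * 1.5,
                 radius_cv = base$radius_cv,
                 peak_intensity = base$peak_intensity * 0.7,
                 intensity_cv = base$intensity_cv)
  } else base
  synthetic_spec(image_height_px, image_width_px, cluster = cl, seed = seed, ...)
}

#' Write a two-condition synthetic dataset to disk
#'
#' Generates `n_images_per_group` images per condition with per-image seeds
#' derived deterministically from the master seed, writes 16-bit TIFF images,
#' 8-bit PNG masks, per-image ground-truth JSON and a labels CSV.
#'
#' @param control,invasive [synthetic_spec()] for each condition (their `seed`
#'   fields are overridden by the derived per-image seeds).
#' @param n_images_per_group images per condition (>= 1).
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return invisibly, the labels data.frame (with a `labels_path` attribute).
#' @export
simulate_group_dataset <- function(control, invasive, n_images_per_group,
                                   out_dir, seed = 1L) {
  stopifnot(inherits(control, "synthetic_spec"),
            inherits(invasive, "synthetic_spec"),
            n_images_per_group >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory '", out_dir, "'")
  specs <- list(control = control, invasive = invasive)
  rows <- list()
  k <- 0L
  for (g in names(specs)) {
    for (i in seq_len(n_images_per_group)) {
      k <- k + 1L
      sp <- specs[[g]]
      sp$seed <- as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
      sim <- simulate_cell_image(sp)
      stem <- sprintf("%s_%02d", g, i)
      img_path <- file.path(out_dir, paste0(stem, ".tif"))
      mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
      gt_path <- file.path(out_dir, paste0(stem, "_truth.json"))
      write_intensity_image(sim$image, img_path)
      write_roi_mask(sim$mask, mask_path)
      jsonlite::write_json(
        list(centres = unname(sim$ground_truth$centres),
             radii_px = sim$ground_truth$radii_px,
             peaks = sim$ground_truth$peaks,
             seed = sp$seed),
        gt_path, digits = NA)
      rows[[k]] <- data.frame(image_path = basename(img_path),
                              mask_path = basename(mask_path),
                              group = g, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  labels_path <- file.path(out_dir, "labels.csv")
  utils::write.csv(labels, labels_path, row.names = FALSE)
  attr(labels, "labels_path") <- labels_path
  invisible(labels)
}
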