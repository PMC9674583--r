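# Pipeline orchestration: configuration, per-image feature extraction,
# group comparison with report files, and the end-to-end run.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis. All defaults follow the documented
#' procedure: 100-px blocks excluding truncated edge remainders, per-block
#' Otsu with no minimum patch size, 64-level symmetric GLCMs at the twelve
#' standard offsets, and 10000 bootstrap replicates.
#'
#' @param block_size_px grid block edge (default 100).
#' @param include_truncated_edge_blocks keep partial edge blocks?
#' @param pixel_size_nm physical pixel size attached to loaded images.
#' @param min_patch_area_px minimum patch size in pixels (default 1).
#' @param glcm a [glcm_config()].
#' @param n_boot,conf_level,pooling,correction see [compare_groups()].
#' @param features feature columns compared by default.
#' @param seed integer seed used by all stochastic steps.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(block_size_px = 100L,
                            include_truncated_edge_blocks = FALSE,
                            pixel_size_nm = 25,
                            min_patch_area_px = 1L,
                            glcm = glcm_config(),
                            n_boot = 10000L, conf_level = 0.95,
                            pooling = "block", correction = "none",
                            features = DEFAULT_COMPARE_FEATURES,
                            seed = 1L) {
  structure(list(block_size_px = as.integer(block_size_px),
                 include_truncated_edge_blocks = include_truncated_edge_blocks,
                 pixel_size_nm = pixel_size_nm,
                 min_patch_area_px = as.integer(min_patch_area_px),
                 glcm = glcm, n_boot = as.integer(n_boot),
                 conf_level = conf_level, pooling = pooling,
                 correction = correction, features = features,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the [pipeline_config()] arguments; GLCM settings
#' nest under `glcm` (keys `levels`, `quantization`, `symmetric`,
#' `homogeneity_form`, `global_range`). Missing keys take the defaults.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  gl <- do.call(glcm_config, raw$glcm %||% list())
  args <- raw[setdiff(names(raw), "glcm")]
  args <- args[names(args) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, c(args, list(glcm = gl)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract per-block features from one image/mask pair
#'
#' Tiles the image, selects the blocks overlapping the ROI, and computes
#' patch statistics and invariant texture features for each. Fails (rather
#' than silently skipping) when no block is selected, since that would change
#' the statistical sample.
#'
#' @param image [sted_image] (or numeric matrix).
#' @param mask `roi_mask` (or logical matrix) of the same shape.
#' @param config a [pipeline_config()].
#' @param image_id,group identifiers copied into the output rows.
#' @return data.frame in the feature-table schema, one row per selected
#'   block.
#' @export
extract_image_features <- function(image, mask, config = pipeline_config(),
                                   image_id = "image", group = NA_character_) {
  if (!identical(dim(unclass(image)), dim(unclass(mask))))
    stop("image ", paste(dim(image), collapse = "x"), " and mask ",
         paste(dim(mask), collapse = "x"), " shapes differ for '", image_id, "'")
  grid <- build_grid(image, config$block_size_px,
                     config$include_truncated_edge_blocks)
  sel <- select_blocks(grid, mask, dim(unclass(image)))
  if (nrow(sel) == 0L)
    stop("no blocks selected for image '", image_id,
         "': the markup does not overlap the grid")
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    px <- block_pixels(image, sel[i, ])
    ps <- patch_statistics(px, config$min_patch_area_px)
    tx <- block_texture(px, config$glcm)
    data.frame(image_id = image_id, group = group,
               block_row = sel$block_row[i], block_col = sel$block_col[i],
               n_pixels_in_block = length(px),
               patch_count = ps$patch_count,
               mean_patch_area_px = ps$mean_patch_area_px,
               mean_fg_intensity = ps$mean_fg_intensity,
               mean_intensity_per_patch = ps$mean_intensity_per_patch,
               otsu_threshold = ps$otsu_threshold,
               energy = tx$energy, contrast = tx$contrast,
               homogeneity = tx$homogeneity,
               heterogeneity = tx$heterogeneity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run feature extraction over a labelled dataset
#'
#' @param labels data.frame from [read_labels()] (or a path to a labels CSV).
#' @param config a [pipeline_config()].
#' @param out_csv optional path; when given, the feature table is written
#'   there with [write_feature_table()].
#' @param verbose log per-image block counts to stderr.
#' @return the feature table (one row per selected block per image).
#' @export
run_extract <- function(labels, config = pipeline_config(), out_csv = NULL,
                        verbose = TRUE) {
  if (is.character(labels)) labels <- read_labels(labels)
  tabs <- lapply(seq_len(nrow(labels)), function(i) {
    img <- read_intensity_image(labels$image_path[i], config$pixel_size_nm)
    msk <- read_roi_mask(labels$mask_path[i], dim(unclass(img)))
    ft <- extract_image_features(img, msk, config,
                                 image_id = basename(labels$image_path[i]),
                                 group = labels$group[i])
    if (verbose)
      message(sprintf("  %s [%s]: %d selected block(s)",
                      basename(labels$image_path[i]), labels$group[i],
                      nrow(ft)))
    ft
  })
  features <- do.call(rbind, tabs)
  if (!is.null(out_csv)) write_feature_table(features, out_csv)
  features
}

#' Compare groups and write report files
#'
#' Wraps [compare_groups()] and writes the comparison report as CSV (one row
#' per feature) and JSON (results plus every configuration value, for
#' provenance).
#'
#' @param features feature table (data.frame or CSV path).
#' @param group_a,group_b group labels to compare.
#' @param config a [pipeline_config()].
#' @param out_prefix when given, writes `<out_prefix>.csv` and
#'   `<out_prefix>.json`.
#' @return the `sted_comparison` object, invisibly when writing.
#' @export
run_compare <- function(features, group_a, group_b,
                        config = pipeline_config(), out_prefix = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  cmp <- compare_groups(features, group_a, group_b,
                        feature_names = config$features,
                        n_boot = config$n_boot, seed = config$seed,
                        conf_level = config$conf_level,
                        pooling = config$pooling,
                        correction = config$correction)
  if (!is.null(out_prefix)) {
    utils::write.csv(cmp$results, paste0(out_prefix, ".csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(group_a = group_a, group_b = group_b,
           results = cmp$results,
           config = config_as_list(config)),
      paste0(out_prefix, ".json"), digits = NA, auto_unbox = TRUE)
    return(invisible(cmp))
  }
  cmp
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$glcm <- unclass(cfg$glcm)
  cfg$glcm$offsets <- NULL                       # standard twelve, documented
  cfg
}

#' End-to-end pipeline: simulate, extract, compare
#'
#' Generates a two-condition synthetic dataset, extracts per-block features
#' and compares the conditions, writing all intermediate files under
#' `out_dir`. A single seed makes the whole run reproducible byte for byte.
#'
#' @param out_dir output directory.
#' @param control,invasive [synthetic_spec()]s (defaults: the built-in
#'   presets).
#' @param n_per_group images per condition.
#' @param config a [pipeline_config()].
#' @param seed master seed (also used for the comparison bootstrap).
#' @param verbose log progress.
#' @return list with `features` (data.frame) and `comparison`
#'   (`sted_comparison`).
#' @export
run_pipeline <- function(out_dir,
                         control = preset_spec("control"),
                         invasive = preset_spec("invasive"),
                         n_per_group = 3L,
                         config = pipeline_config(),
                         seed = config$seed, verbose = TRUE) {
  config$seed <- as.integer(seed)
  labels <- simulate_group_dataset(control, invasive, n_per_group,
                                   out_dir, seed = seed)
  labels <- read_labels(attr(labels, "labels_path"), require_groups = 2L)
  features <- run_extract(labels, config,
                          out_csv = file.path(out_dir, "features.csv"),
                          verbose = verbose)
  cmp <- run_compare(features, "control", "invasive", config,
                     out_prefix = file.path(out_dir, "comparison"))
  list(features = features, comparison = cmp)
}
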