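#' Pipeline configuration
#'
#' Houses every numeric constant the morphometry pipeline uses. All lengths
#' are in micrometers and are converted to pixels only through
#' [microns_to_pixels()], so one configuration behaves identically across
#' x20 and x40 scans.
#'
#' @param window_um Sliding-window edge for tile-based segmentation (50 um;
#'   99 px at x20).
#' @param proper_stroma_width_um Width of the normal stromal rim around each
#'   tissue structure that is excluded from fibrosis accounting. Valid range
#'   15-20 um; the default is the lower bound, 15.
#' @param lymphocyte_axis_ratio_max Upper bound (exclusive) on the fitted
#'   ellipse semi-axis ratio for a cell to count as a lymphocyte; 2.
#' @param lymphocyte_brightness_max Upper bound (exclusive) on mean grayscale
#'   brightness (0-255) for a lymphocyte; 95.
#' @param infiltration_tile_um Edge of the square grid tile used for
#'   infiltration mapping; 50 um.
#' @param infiltration_min_lymphocytes Minimum lymphocytes per tile; 2.
#' @param infiltration_min_nuclei Minimum total detected cells per tile; 20.
#' @param count_lymphocytes_as_nuclei If `TRUE` (default) the 20-cell rule
#'   counts every detected cell, lymphocytes included, since lymphocyte
#'   nuclei are nuclei; `FALSE` counts non-lymphocyte nuclei only.
#' @param merge_iou_min Overlap threshold in (0, 1] above which same-class
#'   instances are considered one structure and merged.
#' @param merge_criterion `"overlap"` (intersection over the smaller mask;
#'   default, robust to window clipping) or `"iou"` (intersection over
#'   union).
#' @param border_discard_area_um2 Window-border instances smaller than this
#'   are discarded as unstable; 100 um^2.
#' @param tissue_threshold Grayscale cutoff below which a pixel is tissue,
#'   or `"otsu"` for automatic thresholding.
#' @param cell_threshold_max Upper cap on the Otsu threshold used for dark
#'   cell candidates within the stroma (gray 0-255).
#' @param nucleus_area_range_um2 Size gate (um^2) for any detected nucleus;
#'   default equivalent diameter 4-15 um.
#' @param lymphocyte_area_range_um2 Size gate (um^2) for lymphocytes;
#'   default equivalent diameter 4-10 um.
#' @param include_proper_stroma_in_cell_search Search for cells in the
#'   proper stromal rim as well as the fibrosis-eligible stroma (default
#'   `TRUE`).
#'
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$window_um
#' @export
pipeline_config <- function(window_um = 50,
                            proper_stroma_width_um = 15,
                            lymphocyte_axis_ratio_max = 2,
                            lymphocyte_brightness_max = 95,
                            infiltration_tile_um = 50,
                            infiltration_min_lymphocytes = 2L,
                            infiltration_min_nuclei = 20L,
                            count_lymphocytes_as_nuclei = TRUE,
                            merge_iou_min = 0.5,
                            merge_criterion = c("overlap", "iou"),
                            border_discard_area_um2 = 100,
                            tissue_threshold = 230,
                            cell_threshold_max = 180,
                            nucleus_area_range_um2 = equiv_diameter_area(c(4, 15)),
                            lymphocyte_area_range_um2 = equiv_diameter_area(c(4, 10)),
                            include_proper_stroma_in_cell_search = TRUE) {
  merge_criterion <- match.arg(merge_criterion)
  cfg <- list(
    window_um = as.numeric(window_um),
    proper_stroma_width_um = as.numeric(proper_stroma_width_um),
    lymphocyte_axis_ratio_max = as.numeric(lymphocyte_axis_ratio_max),
    lymphocyte_brightness_max = as.numeric(lymphocyte_brightness_max),
    infiltration_tile_um = as.numeric(infiltration_tile_um),
    infiltration_min_lymphocytes = as.integer(infiltration_min_lymphocytes),
    infiltration_min_nuclei = as.integer(infiltration_min_nuclei),
    count_lymphocytes_as_nuclei = isTRUE(count_lymphocytes_as_nuclei),
    merge_iou_min = as.numeric(merge_iou_min),
    merge_criterion = merge_criterion,
    border_discard_area_um2 = as.numeric(border_discard_area_um2),
    tissue_threshold = if (is.character(tissue_threshold)) tissue_threshold
                       else as.numeric(tissue_threshold),
    cell_threshold_max = as.numeric(cell_threshold_max),
    nucleus_area_range_um2 = as.numeric(nucleus_area_range_um2),
    lymphocyte_area_range_um2 = as.numeric(lymphocyte_area_range_um2),
    include_proper_stroma_in_cell_search =
      isTRUE(include_proper_stroma_in_cell_search)
  )
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Area of a circle from its equivalent diameter
#'
#' @param diameter_um Diameter(s) in micrometers.
#' @return Area(s) in um^2.
#' @export
equiv_diameter_area <- function(diameter_um) pi * (diameter_um / 2)^2

validate_config <- function(cfg) {
  num_pos <- c("window_um", "proper_stroma_width_um",
               "lymphocyte_axis_ratio_max", "lymphocyte_brightness_max",
               "infiltration_tile_um", "border_discard_area_um2",
               "cell_threshold_max")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config field `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$merge_iou_min <= 0 || cfg$merge_iou_min > 1) {
    stop("`merge_iou_min` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$infiltration_min_lymphocytes < 0 || cfg$infiltration_min_nuclei < 0) {
    stop("infiltration count thresholds must be nonnegative", call. = FALSE)
  }
  for (f in c("nucleus_area_range_um2", "lymphocyte_area_range_um2")) {
    v <- cfg[[f]]
    if (length(v) != 2L || any(v <= 0) || v[1] > v[2]) {
      stop("config field `", f, "` must be an increasing positive pair",
           call. = FALSE)
    }
  }
  tt <- cfg$tissue_threshold
  ok_tt <- (is.numeric(tt) && length(tt) == 1L && tt > 0 && tt < 256) ||
    identical(tt, "otsu")
  if (!ok_tt) {
    stop("`tissue_threshold` must be a gray level in (0, 256) or \"otsu\"",
         call. = FALSE)
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-36s %s\n", f, paste(format(x[[f]]), collapse = " - ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The file holds one key per configuration field, lengths in micrometers.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults. The default configuration round-trips losslessly.
#'
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}
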