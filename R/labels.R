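#' Tissue class labels
#'
#' The closed label set used throughout the pipeline. Glomeruli, tubuli and
#' arteries are "structure" classes and are the only classes a segmenter may
#' emit; stroma, the proper stromal space and infiltration are derived by the
#' pipeline itself; background is non-tissue.
#'
#' @return Character vector of the seven class names, in code order.
#' @export
class_labels <- function() {
  c("background", "glomeruli", "tubuli", "arteries",
    "stroma", "proper_stroma", "infiltration")
}

#' @rdname class_labels
#' @export
structure_classes <- function() c("glomeruli", "tubuli", "arteries")

# integer codes for label_map rasters; background is 0
label_code <- function(label) {
  codes <- stats::setNames(seq_along(class_labels()) - 1L, class_labels())
  unknown <- setdiff(label, names(codes))
  if (length(unknown)) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(codes[label])
}

assert_structure_class <- function(label) {
  if (!label %in% structure_classes()) {
    stop("class label must be a structure class (",
         paste(structure_classes(), collapse = ", "), "), got: ", label,
         call. = FALSE)
  }
  label
}

#' Per-class display palette
#'
#' Colours follow the conventional overlay scheme for renal cortex
#' segmentation masks: glomeruli orange, tubules blue, arteries green,
#' stroma grey, proper stromal space light blue, infiltration brown.
#'
#' @return Named character vector of hex colours, one per class label.
#' @export
label_palette <- function() {
  c(background    = "#FFFFFF",
    glomeruli     = "#E69F00",
    tubuli        = "#3366CC",
    arteries      = "#2CA02C",
    stroma        = "#9E9E9E",
    proper_stroma = "#A6D8F0",
    infiltration  = "#8C510A")
}

#' Construct a label map
#'
#' A label map is a per-pixel semantic raster: an integer matrix of class
#' codes together with a calibration and the slide-coordinate offset of its
#' pixel (0, 0). Matrices are indexed `[y + 1, x + 1]` for zero-based pixel
#' coordinates (x, y); boxes are half-open `[x0, x1) x [y0, y1)`.
#'
#' @param labels Integer matrix of class codes (0-6) or character matrix of
#'   class names.
#' @param calibration A [pixel_calibration()].
#' @param origin Length-2 integer, slide-coordinate (x, y) of pixel (0, 0).
#'
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, calibration, origin = c(0L, 0L)) {
  assert_calibration(calibration)
  if (is.character(labels)) {
    lab <- matrix(label_code(labels), nrow = nrow(labels))
  } else {
    lab <- labels
    storage.mode(lab) <- "integer"
    if (any(lab < 0L | lab > 6L, na.rm = TRUE) || anyNA(lab)) {
      stop("label codes must be integers in 0..6", call. = FALSE)
    }
  }
  structure(
    list(labels = lab, calibration = calibration,
         origin = as.integer(origin)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d px at %.4f um/px\n",
              d[2], d[1], x$calibration$pixel_size_um))
  tab <- table(factor(class_labels()[x$labels + 1L], levels = class_labels()))
  pct <- 100 * tab / length(x$labels)
  for (k in names(tab)) {
    if (tab[[k]] > 0) cat(sprintf("  %-14s %9d px (%5.1f%%)\n", k, tab[[k]], pct[[k]]))
  }
  invisible(x)
}

# logical mask of one or more classes
label_mask <- function(lmap, labels) {
  codes <- label_code(labels)
  matrix(lmap$labels %in% codes, nrow = nrow(lmap$labels))
}

#' Per-class areas of a label map
#'
#' @param lmap A [label_map()].
#' @return A tibble with one row per class present: label, pixel count,
#'   area in um^2 and percentage of the raster.
#' @export
label_areas <- function(lmap) {
  stopifnot(inherits(lmap, "label_map"))
  tab <- table(factor(class_labels()[lmap$labels + 1L], levels = class_labels()))
  tibble::tibble(
    label = names(tab),
    n_px = as.integer(tab),
    area_um2 = as.numeric(tab) * pixel_area_um2(lmap$calibration),
    pct_of_raster = 100 * as.numeric(tab) / length(lmap$labels)
  )
}

#' Render a label map (or RGB array) with ggplot2
#'
#' @param object A `label_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_map <- function(object, ...) {
  lab <- object$labels
  df <- tidyr::expand_grid(y = seq_len(nrow(lab)) - 1L,
                           x = seq_len(ncol(lab)) - 1L)
  df$label <- factor(class_labels()[lab[cbind(df$y + 1L, df$x + 1L)] + 1L],
                     levels = class_labels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = label_palette(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "class") +
    ggplot2::theme_minimal()
}
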