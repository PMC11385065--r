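# Slide analysis orchestration: tissue detection, sliding-window
# segmentation through a pluggable segmenter, and stroma derivation.

#' Detect tissue by grayscale intensity thresholding
#'
#' A pixel is tissue iff its luminance (Rec. 601, 0-255) falls below the
#' threshold; glass background on an H&E scan is near-white. The threshold
#' is either a fixed gray level or `"otsu"`.
#'
#' @param rgb `h x w x 3` array with values in 0-255 (or a single-channel
#'   matrix already in gray levels).
#' @param threshold Gray level in (0, 256) or `"otsu"`.
#' @return Logical `h x w` tissue mask.
#' @export
detect_tissue <- function(rgb, threshold = 230) {
  gray <- if (length(dim(rgb)) == 3) to_grayscale(rgb) else rgb
  if (identical(threshold, "otsu")) {
    v <- as.vector(gray)
    if (max(v) - min(v) < 1e-8) {
      stop("degenerate histogram: image has a single gray level, ",
           "cannot apply Otsu thresholding", call. = FALSE)
    }
    threshold <- otsu_threshold(v)
  }
  gray < threshold
}

#' Scan a slide with a sliding window and a pluggable segmenter
#'
#' Windows of `config$window_um` (99 px at x20) tile the bounding box of
#' the tissue mask with 50% overlap (stride = half the window edge; the
#' last row/column is shifted flush with the box). The segmenter is called
#' on each window that contains tissue and must return instances in
#' tile-local pixel coordinates; instances touching the window border with
#' area below `config$border_discard_area_um2` are discarded as unstable,
#' and survivors are translated to slide coordinates. The returned list is
#' unmerged; pass it to [merge_instances()].
#'
#' @param rgb Slide image, `h x w x 3`, 0-255.
#' @param tissue Logical tissue mask from [detect_tissue()].
#' @param segmenter `function(tile_rgb, calibration, tile_box)` returning a
#'   list of [instance_mask()] in tile coordinates, structure classes only.
#' @param config A [pipeline_config()].
#' @param calib A [pixel_calibration()].
#' @return List of [instance_mask()] in slide coordinates.
#' @export
scan_slide <- function(rgb, tissue, segmenter, config, calib) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_calibration(calib)
  h <- nrow(tissue); w <- ncol(tissue)
  w_px <- microns_to_pixels(config$window_um, calib)
  if (w_px > h || w_px > w) {
    stop("tiling error: window (", w_px, " px) larger than the image",
         call. = FALSE)
  }
  if (!any(tissue)) return(list())
  rows <- range(which(rowSums(tissue) > 0))
  cols <- range(which(colSums(tissue) > 0))
  bx0 <- cols[1] - 1L; bx1 <- cols[2]            # half-open, 0-based
  by0 <- rows[1] - 1L; by1 <- rows[2]
  starts <- function(a0, a1, n) {
    if (a1 - a0 <= w_px) return(max(0L, min(a0, n - w_px)))
    s <- seq(a0, a1 - w_px, by = max(1L, w_px %/% 2L))
    unique(c(s, a1 - w_px))
  }
  min_area_px <- config$border_discard_area_um2 / pixel_area_um2(calib)
  out <- list()
  for (y0 in starts(by0, by1, h)) {
    for (x0 in starts(bx0, bx1, w)) {
      x1 <- min(x0 + w_px, w); y1 <- min(y0 + w_px, h)
      if (!any(tissue[(y0 + 1):y1, (x0 + 1):x1])) next
      tile_box <- c(x0, y0, x1, y1)
      tile_rgb <- rgb[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
      found <- segmenter(tile_rgb, calib, tile_box)
      for (inst in found) {
        b <- inst$bbox
        touches <- b[1] <= 0L || b[2] <= 0L ||
          b[3] >= (x1 - x0) || b[4] >= (y1 - y0)
        if (touches && instance_area_px(inst) < min_area_px) next
        out[[length(out) + 1]] <- instance_mask(
          inst$class_label, inst$mask,
          offset = inst$bbox[1:2] + c(x0, y0), score = inst$score)
      }
    }
  }
  out
}

#' Rasterize a region-of-interest polygon
#'
#' Even-odd (crossing-number) scanline fill evaluated at pixel centers.
#' Vertices are in pixel units, 0-based, with pixel (x, y) covering the
#' unit square whose center is (x + 0.5, y + 0.5).
#'
#' @param vertices Two-column matrix of (x, y) polygon vertices; the
#'   polygon closes itself.
#' @param dim Raster dimensions `c(h, w)`.
#' @return Logical `h x w` mask.
#' @export
rasterize_polygon <- function(vertices, dim) {
  h <- dim[1]; w <- dim[2]
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  out <- matrix(FALSE, h, w)
  for (row in seq_len(h)) {
    yc <- row - 0.5
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > yc) != (vy[j] > yc)) {
        xs <- c(xs, vx[i] + (yc - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- max(1L, ceiling(xs[k] + 0.5))
        c1 <- min(w, floor(xs[k + 1] + 0.5))
        if (c0 <= c1) out[row, c0:c1] <- TRUE
      }
    }
  }
  out
}

#' Derive the stromal compartment and proper stromal space
#'
#' Tissue not assigned to a structure class is stroma. A thin rim of
#' normal stroma (`config$proper_stroma_width_um`, conventionally
#' 15-20 um) hugs every tissue structure; it is carved out of the stroma
#' by a Euclidean-distance dilation of the merged structure union and
#' labelled `proper_stroma`, leaving the remainder as the
#' fibrosis-eligible compartment. Structures, stroma and proper stroma are
#' clipped to the region of interest; everything else is background.
#'
#' @param tissue Logical tissue mask.
#' @param instances Merged [instance_mask()] list.
#' @param config A [pipeline_config()].
#' @param calib A [pixel_calibration()].
#' @param roi Optional ROI: a logical mask of the same shape or a
#'   two-column vertex matrix (px) for [rasterize_polygon()]. Default is
#'   the whole raster.
#' @return A [label_map()].
#' @export
derive_stroma <- function(tissue, instances, config, calib, roi = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_calibration(calib)
  h <- nrow(tissue); w <- ncol(tissue)
  roi_mask <- if (is.null(roi)) {
    matrix(TRUE, h, w)
  } else if (is.matrix(roi) && is.logical(roi)) {
    roi
  } else {
    rasterize_polygon(roi, c(h, w))
  }
  if (!any(roi_mask & tissue)) {
    stop("empty region: the ROI contains no tissue", call. = FALSE)
  }
  codes <- matrix(0L, h, w)
  struct_union <- matrix(FALSE, h, w)
  for (cl in structure_classes()) {
    cl_mask <- matrix(FALSE, h, w)
    for (inst in instances) {
      if (inst$class_label != cl) next
      b <- inst$bbox
      cl_mask[(b[2] + 1):b[4], (b[1] + 1):b[3]] <-
        cl_mask[(b[2] + 1):b[4], (b[1] + 1):b[3]] | inst$mask
    }
    codes[cl_mask & roi_mask] <- label_code(cl)
    struct_union <- struct_union | cl_mask
  }
  stroma <- tissue & !struct_union & roi_mask
  ring_px <- config$proper_stroma_width_um / calib$pixel_size_um
  if (any(struct_union)) {
    dstruct <- as.matrix(EBImage::distmap(!struct_union))
    proper <- stroma & (dstruct <= ring_px)
  } else {
    proper <- matrix(FALSE, h, w)
  }
  codes[stroma] <- label_code("stroma")
  codes[proper] <- label_code("proper_stroma")
  label_map(codes, calib)
}
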