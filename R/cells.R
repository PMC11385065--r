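# Nucleus and lymphocyte detection in the stromal compartment, and mapping
# of interstitial infiltration on a fixed 50 um grid.

# Otsu threshold of a numeric vector on the 0-255 scale. (EBImage's otsu()
# operates on a whole image; the cell detector needs it restricted to the
# stromal pixels only, so the histogram criterion is evaluated here.)
otsu_threshold <- function(v, levels = 256) {
  counts <- tabulate(pmin(pmax(floor(v), 0), levels - 1) + 1L, nbins = levels)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 1))
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L + 0.5
}

#' Detect nuclei and lymphocytes within the stroma
#'
#' Dark objects inside the stromal compartment (including the proper
#' stromal rim unless configured otherwise) are found by grayscale
#' thresholding -- Otsu restricted to stromal pixels, capped at
#' `config$cell_threshold_max` -- and touching objects are split by
#' watershed on the distance transform. A moment-based ellipse is fitted
#' to each object; objects outside both size gates are discarded. A cell
#' is a lymphocyte iff its semi-axis ratio is below
#' `lymphocyte_axis_ratio_max` (2), its mean gray brightness below
#' `lymphocyte_brightness_max` (95) and its area within the lymphocyte
#' gate; otherwise it is a nucleus if within the nucleus gate.
#'
#' @param rgb Slide image, `h x w x 3`, 0-255.
#' @param lmap A [label_map()] from [derive_stroma()].
#' @param config A [pipeline_config()].
#' @return A tibble of detected cells: centroid (px and um), semi-axes
#'   (um), `axis_ratio`, `mean_brightness`, `area_um2`, `cell_type`.
#' @export
detect_cells <- function(rgb, lmap, config) {
  stopifnot(inherits(lmap, "label_map"), inherits(config, "pipeline_config"))
  calib <- lmap$calibration
  px <- calib$pixel_size_um
  search_labels <- c("stroma", "infiltration",
                     if (config$include_proper_stroma_in_cell_search)
                       "proper_stroma")
  region <- label_mask(lmap, search_labels)
  if (!any(region)) {
    stop("stroma mask is empty; run derive_stroma() first", call. = FALSE)
  }
  gray <- if (length(dim(rgb)) == 3) to_grayscale(rgb) else rgb
  thr <- min(otsu_threshold(gray[region]), config$cell_threshold_max)
  candidates <- region & (gray < thr)
  empty <- cells_empty_tibble()
  if (!any(candidates)) return(empty)
  dm <- EBImage::distmap(candidates)
  labels <- as.matrix(EBImage::watershed(dm, tolerance = 1))
  n_obj <- max(labels)
  if (n_obj == 0) return(empty)

  nz <- which(labels > 0)
  obj <- labels[nz]
  ys <- (nz - 1L) %% nrow(labels)                # 0-based pixel coords
  xs <- (nz - 1L) %/% nrow(labels)
  gvals <- gray[nz]
  area_px <- tabulate(obj, nbins = n_obj)
  cx <- tapply(xs, obj, mean)
  cy <- tapply(ys, obj, mean)
  # central second moments -> equivalent ellipse semi-axes
  mxx <- tapply(seq_along(obj), obj, function(i) {
    stats::var(xs[i]) * (length(i) - 1) / length(i)
  })
  myy <- tapply(seq_along(obj), obj, function(i) {
    stats::var(ys[i]) * (length(i) - 1) / length(i)
  })
  mxy <- tapply(seq_along(obj), obj, function(i) {
    if (length(i) < 2) return(0)
    sum((xs[i] - mean(xs[i])) * (ys[i] - mean(ys[i]))) / length(i)
  })
  mxx[is.na(mxx)] <- 0; myy[is.na(myy)] <- 0; mxy[is.na(mxy)] <- 0
  common <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (mxx + myy + common) / 2                  # eigenvalues
  l2 <- (mxx + myy - common) / 2
  semi_major_px <- 2 * sqrt(pmax(l1, 1e-9))
  semi_minor_px <- 2 * sqrt(pmax(l2, 1e-9))
  brightness <- tapply(gvals, obj, mean)

  ids <- sort(unique(obj))
  tb <- tibble::tibble(
    x_px = as.numeric(cx[as.character(ids)]),
    y_px = as.numeric(cy[as.character(ids)]),
    semi_axis_major_um = as.numeric(semi_major_px[as.character(ids)]) * px,
    semi_axis_minor_um = as.numeric(semi_minor_px[as.character(ids)]) * px,
    mean_brightness = as.numeric(brightness[as.character(ids)]),
    area_um2 = area_px[ids] * px^2
  )
  tb$x_um <- tb$x_px * px
  tb$y_um <- tb$y_px * px
  tb$axis_ratio <- tb$semi_axis_major_um / pmax(tb$semi_axis_minor_um, 1e-9)

  lg <- config$lymphocyte_area_range_um2
  ng <- config$nucleus_area_range_um2
  in_lymph_gate <- tb$area_um2 >= lg[1] & tb$area_um2 <= lg[2]
  in_nucleus_gate <- tb$area_um2 >= ng[1] & tb$area_um2 <= ng[2]
  is_lymph <- in_lymph_gate &
    tb$axis_ratio < config$lymphocyte_axis_ratio_max &
    tb$mean_brightness < config$lymphocyte_brightness_max
  tb$cell_type <- ifelse(is_lymph, "lymphocyte",
                         ifelse(in_nucleus_gate, "nucleus", NA_character_))
  tb <- tb[!is.na(tb$cell_type), , drop = FALSE]
  tb[, c("x_px", "y_px", "x_um", "y_um", "semi_axis_major_um",
         "semi_axis_minor_um", "axis_ratio", "mean_brightness",
         "area_um2", "cell_type")]
}

cells_empty_tibble <- function() {
  tibble::tibble(x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
                 y_um = numeric(0), semi_axis_major_um = numeric(0),
                 semi_axis_minor_um = numeric(0), axis_ratio = numeric(0),
                 mean_brightness = numeric(0), area_um2 = numeric(0),
                 cell_type = character(0))
}

#' Map interstitial infiltration on a fixed grid
#'
#' The region of interest is covered by a fixed (non-sliding) grid of
#' square tiles with edge `config$infiltration_tile_um` (50 um), anchored
#' at the ROI bounding-box origin. A tile is flagged as infiltrated iff it
#' contains at least `infiltration_min_lymphocytes` lymphocytes and at
#' least `infiltration_min_nuclei` detected cells (all detected cells by
#' default, since lymphocyte nuclei are nuclei; set
#' `count_lymphocytes_as_nuclei = FALSE` for the strict reading). The
#' infiltration mask is the union of flagged tiles intersected with the
#' fibrosis-eligible stroma, and the label map is updated accordingly.
#'
#' @param cells Tibble from [detect_cells()].
#' @param lmap A [label_map()] from [derive_stroma()].
#' @param config A [pipeline_config()].
#' @param grid_origin Pixel (x, y) anchoring the tile grid; default the
#'   raster origin `c(0, 0)`.
#' @return List with `label_map` (updated), `tiles` (tibble: tile_x,
#'   tile_y, n_lymphocytes, n_cells, flagged) and `mask` (logical raster).
#' @export
map_infiltration <- function(cells, lmap, config, grid_origin = c(0L, 0L)) {
  stopifnot(inherits(lmap, "label_map"), inherits(config, "pipeline_config"))
  calib <- lmap$calibration
  tile_px <- microns_to_pixels(config$infiltration_tile_um, calib)
  h <- nrow(lmap$labels); w <- ncol(lmap$labels)
  nty <- ceiling((h - grid_origin[2]) / tile_px)
  ntx <- ceiling((w - grid_origin[1]) / tile_px)
  tiles <- tidyr::expand_grid(tile_y = seq_len(nty) - 1L,
                              tile_x = seq_len(ntx) - 1L)
  if (nrow(cells)) {
    tx <- floor((cells$x_px - grid_origin[1]) / tile_px)
    ty <- floor((cells$y_px - grid_origin[2]) / tile_px)
    keyed <- tibble::tibble(tile_x = tx, tile_y = ty,
                            lymph = cells$cell_type == "lymphocyte")
    counts <- dplyr::summarise(
      dplyr::group_by(keyed, .data$tile_x, .data$tile_y),
      n_lymphocytes = sum(.data$lymph),
      n_cells = dplyr::n(), .groups = "drop")
    tiles <- dplyr::left_join(tiles, counts, by = c("tile_x", "tile_y"))
    tiles$n_lymphocytes[is.na(tiles$n_lymphocytes)] <- 0L
    tiles$n_cells[is.na(tiles$n_cells)] <- 0L
  } else {
    tiles$n_lymphocytes <- 0L
    tiles$n_cells <- 0L
  }
  n_for_rule <- if (config$count_lymphocytes_as_nuclei) tiles$n_cells else
    tiles$n_cells - tiles$n_lymphocytes
  tiles$flagged <- tiles$n_lymphocytes >= config$infiltration_min_lymphocytes &
    n_for_rule >= config$infiltration_min_nuclei

  eligible <- label_mask(lmap, "stroma")
  mask <- matrix(FALSE, h, w)
  flagged <- tiles[tiles$flagged, , drop = FALSE]
  for (i in seq_len(nrow(flagged))) {
    x0 <- grid_origin[1] + flagged$tile_x[i] * tile_px
    y0 <- grid_origin[2] + flagged$tile_y[i] * tile_px
    xs <- max(x0 + 1, 1):min(x0 + tile_px, w)
    ys <- max(y0 + 1, 1):min(y0 + tile_px, h)
    mask[ys, xs] <- TRUE
  }
  mask <- mask & eligible
  codes <- lmap$labels
  codes[mask] <- label_code("infiltration")
  list(label_map = label_map(codes, calib, lmap$origin),
       tiles = tiles, mask = mask)
}

#' Morphometry report for one region of interest
#'
#' Tissue is every non-background pixel of the label map. The fibrosis
#' relative area is the fibrosis-eligible stroma (stroma beyond the proper
#' stromal rim, including any infiltrated part) as a percentage of tissue;
#' the infiltration relative area is the infiltrated subset, so fibrosis
#' always contains infiltration.
#'
#' @param lmap A [label_map()] with infiltration mapped.
#' @param cells Tibble from [detect_cells()] (for the cell counts).
#' @param tiles Tibble from [map_infiltration()] (for the tile count);
#'   optional.
#' @param roi_id Identifier copied into the report row.
#' @return One-row tibble: `roi_id`, `tissue_area_um2`,
#'   `fibrosis_rel_area_pct`, `infiltration_rel_area_pct`,
#'   `n_lymphocytes`, `n_nuclei`, `n_infiltration_tiles`.
#' @export
compute_morphometry <- function(lmap, cells = NULL, tiles = NULL,
                                roi_id = "roi") {
  stopifnot(inherits(lmap, "label_map"))
  tissue <- lmap$labels != 0L
  if (!any(tissue)) {
    stop("undefined denominator: label map contains no tissue", call. = FALSE)
  }
  fib <- label_mask(lmap, c("stroma", "infiltration"))
  inf <- label_mask(lmap, "infiltration")
  tibble::tibble(
    roi_id = roi_id,
    tissue_area_um2 = sum(tissue) * pixel_area_um2(lmap$calibration),
    fibrosis_rel_area_pct = area_fraction(fib, tissue),
    infiltration_rel_area_pct = area_fraction(inf, tissue),
    n_lymphocytes = if (is.null(cells)) NA_integer_ else
      sum(cells$cell_type == "lymphocyte"),
    n_nuclei = if (is.null(cells)) NA_integer_ else
      sum(cells$cell_type == "nucleus"),
    n_infiltration_tiles = if (is.null(tiles)) NA_integer_ else
      sum(tiles$flagged)
  )
}
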