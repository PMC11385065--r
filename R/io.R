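# Formats and the end-to-end driver: QuPath-style GeoJSON annotations in
# pixel coordinates (calibration carried in a sidecar field), palette PNG
# label maps, CSV morphometry reports.

# closed rings (pixel corner coordinates) tracing a binary mask; holes are
# separate rings, to be combined with even-odd parity
mask_to_rings <- function(mask, offset = c(0L, 0L)) {
  h <- nrow(mask); w <- ncol(mask)
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- mask * 1
  yv <- (0:(h + 1)) - 0.5                        # continuous y per z row
  xv <- (0:(w + 1)) - 0.5
  cl <- grDevices::contourLines(x = yv, y = xv, z = z, levels = 0.5)
  lapply(cl, function(cc) {
    cbind(x = cc$y + offset[1], y = cc$x + offset[2])
  })
}

# rasterize a set of rings with even-odd parity into an h x w mask whose
# pixel (0,0) sits at `offset` in ring coordinates
rings_to_mask <- function(rings, dim, offset = c(0, 0)) {
  acc <- matrix(FALSE, dim[1], dim[2])
  for (r in rings) {
    v <- cbind(r[, 1] - offset[1], r[, 2] - offset[2])
    acc <- xor(acc, rasterize_polygon(v, dim))
  }
  acc
}

rings_to_geojson_coords <- function(rings) {
  # one GeoJSON Polygon per ring; grouped as a MultiPolygon. Even-odd
  # rasterization on read makes hole orientation immaterial.
  lapply(rings, function(r) {
    pts <- lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    if (!isTRUE(all.equal(r[1, ], r[nrow(r), ], check.attributes = FALSE))) {
      pts <- c(pts, pts[1])
    }
    list(pts)
  })
}

#' Write instances and ROIs as a QuPath-style GeoJSON FeatureCollection
#'
#' Each instance becomes a Feature with a MultiPolygon geometry in pixel
#' coordinates and a `classification$name` property from the closed label
#' set; ROI polygons are Features with `object_type: "roi"` and a free-text
#' label. The pixel size is stored in a top-level `calibration` field.
#'
#' @param instances List of [instance_mask()].
#' @param path Output path.
#' @param calibration A [pixel_calibration()].
#' @param rois Optional named list of two-column vertex matrices (px).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(instances, path, calibration, rois = NULL) {
  assert_calibration(calibration)
  features <- lapply(instances, function(inst) {
    rings <- mask_to_rings(inst$mask, inst$bbox[1:2])
    list(
      type = "Feature",
      geometry = list(type = "MultiPolygon",
                      coordinates = rings_to_geojson_coords(rings)),
      properties = list(
        object_type = "annotation",
        classification = list(name = inst$class_label),
        score = inst$score
      )
    )
  })
  for (nm in names(rois)) {
    r <- rois[[nm]]
    pts <- lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    pts <- c(pts, pts[1])
    features <- c(features, list(list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(pts)),
      properties = list(object_type = "roi",
                        classification = list(name = nm))
    )))
  }
  doc <- list(type = "FeatureCollection",
              calibration = list(pixel_size_um = calibration$pixel_size_um,
                                 magnification = calibration$magnification),
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GeoJSON annotation document
#'
#' Features with `object_type: "roi"` become ROI polygons; every other
#' feature must carry a structure-class name and is rasterized (even-odd,
#' pixel centers) into an [instance_mask()] at the document's calibration.
#'
#' @param path GeoJSON file path.
#' @param calibration Optional [pixel_calibration()]; defaults to the
#'   document's `calibration` field.
#' @return List with `instances`, `rois` (named list of vertex matrices)
#'   and `calibration`.
#' @export
read_annotations <- function(path, calibration = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("parse error: not a GeoJSON FeatureCollection", call. = FALSE)
  }
  if (is.null(calibration)) {
    if (is.null(doc$calibration$pixel_size_um)) {
      stop("no calibration in document; pass `calibration`", call. = FALSE)
    }
    calibration <- pixel_calibration(
      doc$calibration$pixel_size_um,
      doc$calibration$magnification %||% NA_character_)
  }
  instances <- list()
  rois <- list()
  unknown <- character(0)
  for (k in seq_along(doc$features)) {
    ft <- doc$features[[k]]
    cls <- ft$properties$classification$name %||% NA_character_
    geom <- ft$geometry
    rings <- tryCatch(geometry_rings(geom), error = function(e) {
      stop(sprintf("parse error in feature %d: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    if (identical(ft$properties$object_type, "roi")) {
      rois[[if (is.na(cls)) paste0("roi_", k) else cls]] <- rings[[1]]
      next
    }
    if (!cls %in% structure_classes()) {
      unknown <- c(unknown, if (is.na(cls)) "<missing>" else cls)
      next
    }
    allv <- do.call(rbind, rings)
    x0 <- floor(min(allv[, 1])); y0 <- floor(min(allv[, 2]))
    x1 <- ceiling(max(allv[, 1])); y1 <- ceiling(max(allv[, 2]))
    m <- rings_to_mask(rings, c(y1 - y0, x1 - x0), offset = c(x0, y0))
    if (!any(m)) next
    instances[[length(instances) + 1]] <- instance_mask(
      cls, m, offset = c(x0, y0),
      score = as.numeric(ft$properties$score %||% 1))
  }
  if (length(unknown)) {
    stop("unknown class name(s) in annotations: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  list(instances = instances, rois = rois, calibration = calibration)
}

geometry_rings <- function(geom) {
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) < 4) stop("ring has fewer than 4 points")
    m
  }
  if (identical(geom$type, "Polygon")) {
    lapply(geom$coordinates, ring_mat)
  } else if (identical(geom$type, "MultiPolygon")) {
    unlist(lapply(geom$coordinates, function(poly) lapply(poly, ring_mat)),
           recursive = FALSE)
  } else {
    stop("unsupported geometry type: ", geom$type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a label map as a palette PNG
#'
#' Single-channel PNG storing the integer class code (0-6) directly as the
#' 8-bit gray value; the palette is documented in [class_labels()] order.
#'
#' @param lmap A [label_map()].
#' @param path PNG path.
#' @return `path` / a [label_map()].
#' @export
write_label_map <- function(lmap, path) {
  stopifnot(inherits(lmap, "label_map"))
  png::writePNG(lmap$labels / 255, path)
  invisible(path)
}

#' @rdname write_label_map
#' @param calibration A [pixel_calibration()].
#' @export
read_label_map <- function(path, calibration) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_map(matrix(as.integer(round(m * 255)), nrow = nrow(m)), calibration)
}

#' Colour overlay of a label map on the original image
#'
#' @param rgb Slide image `h x w x 3`, 0-255.
#' @param lmap A [label_map()].
#' @param alpha Mask opacity in `[0, 1]`.
#' @return `h x w x 3` array, 0-255.
#' @export
overlay_label_map <- function(rgb, lmap, alpha = 0.5) {
  pal <- grDevices::col2rgb(label_palette())
  out <- rgb
  for (i in 1:3) {
    mask_col <- matrix(pal[i, lmap$labels + 1L], nrow = nrow(lmap$labels))
    out[, , i] <- (1 - alpha) * rgb[, , i] + alpha * mask_col
  }
  out
}

#' Export detected cells as GeoJSON points
#'
#' @param cells Tibble from [detect_cells()].
#' @param path Output path.
#' @param calibration A [pixel_calibration()].
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, path, calibration) {
  features <- lapply(seq_len(nrow(cells)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(cells$x_px[i], cells$y_px[i])),
         properties = list(
           object_type = "detection",
           classification = list(name = cells$cell_type[i]),
           mean_brightness = cells$mean_brightness[i],
           axis_ratio = cells$axis_ratio[i],
           area_um2 = cells$area_um2[i]))
  })
  doc <- list(type = "FeatureCollection",
              calibration = list(pixel_size_um = calibration$pixel_size_um),
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the whole morphometry pipeline on one image
#'
#' Executes tissue detection, sliding-window segmentation, same-class
#' merging, stroma and proper-space derivation, cell detection,
#' infiltration mapping and morphometry in order, optionally writing the
#' label-map PNG, a colour overlay PNG, instance and cell GeoJSON and a
#' CSV report row into `out_dir`.
#'
#' @param rgb Slide image (`h x w x 3` array, 0-255) or a PNG file path.
#' @param segmenter Segmenter closure (see [scan_slide()]), e.g.
#'   [make_oracle_segmenter()] on a synthetic slide.
#' @param calib A [pixel_calibration()] (ignored when `rgb` is a synthetic
#'   slide).
#' @param config A [pipeline_config()].
#' @param roi Optional ROI (logical mask or vertex matrix in px).
#' @param roi_id Identifier for the report row.
#' @param out_dir Optional output directory for artifacts.
#' @return List with `report` (one-row tibble), `label_map`, `instances`
#'   (merged), `cells`, `tiles` and stage timings (`timings`, seconds).
#' @export
run_full_pipeline <- function(rgb, segmenter, calib,
                              config = pipeline_config(), roi = NULL,
                              roi_id = "roi", out_dir = NULL) {
  if (is.character(rgb)) {
    rgb <- png::readPNG(rgb) * 255
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  tissue <- detect_tissue(rgb, config$tissue_threshold)
  timings["detect_tissue"] <- tic() - t0

  t0 <- tic()
  raw <- scan_slide(rgb, tissue, segmenter, config, calib)
  timings["scan_slide"] <- tic() - t0

  t0 <- tic()
  merged <- merge_instances(raw, config$merge_iou_min, config$merge_criterion)
  timings["merge_instances"] <- tic() - t0

  t0 <- tic()
  lmap <- derive_stroma(tissue, merged, config, calib, roi = roi)
  timings["derive_stroma"] <- tic() - t0

  t0 <- tic()
  cells <- detect_cells(rgb, lmap, config)
  timings["detect_cells"] <- tic() - t0

  t0 <- tic()
  infil <- map_infiltration(cells, lmap, config)
  timings["map_infiltration"] <- tic() - t0

  report <- compute_morphometry(infil$label_map, cells, infil$tiles, roi_id)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_label_map(infil$label_map, file.path(out_dir, "label_map.png"))
    png::writePNG(overlay_label_map(rgb, infil$label_map) / 255,
                  file.path(out_dir, "overlay.png"))
    write_annotations(merged, file.path(out_dir, "instances.geojson"), calib)
    write_cells_geojson(cells, file.path(out_dir, "cells.geojson"), calib)
    utils::write.csv(report, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  list(report = report, label_map = infil$label_map, instances = merged,
       cells = cells, tiles = infil$tiles, timings = timings)
}

#' Export a synthetic slide with its full ground truth
#'
#' Writes the RGB PNG, the ground-truth label-map PNG, the instance
#' GeoJSON, the cell table CSV and a one-row truth summary CSV.
#'
#' @param slide A [generate_slide()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_synth_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "synth_slide"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(slide$rgb / 255, file.path(dir, "slide.png"))
  write_label_map(slide$ground_truth, file.path(dir, "label_map.png"))
  write_annotations(slide$instances, file.path(dir, "instances.geojson"),
                    slide$ground_truth$calibration)
  utils::write.csv(slide$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- tibble::tibble(
    true_fibrosis_pct = slide$true_fibrosis_pct,
    true_infiltration_pct = slide$true_infiltration_pct,
    tissue_fraction_pct = slide$tissue_fraction_pct,
    n_instances = length(slide$instances),
    n_cells = nrow(slide$cells),
    seed = slide$params$seed
  )
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
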