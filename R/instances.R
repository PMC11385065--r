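#' Segmented structure instance
#'
#' One segmented tissue structure: a structure class, a binary mask stored
#' cropped to its tight bounding box, the box itself in slide coordinates,
#' and a confidence score. Coordinates are 0-based; boxes are half-open
#' `(x0, y0, x1, y1)` so that width is `x1 - x0`. The mask matrix is indexed
#' `[y - y0 + 1, x - x0 + 1]`.
#'
#' @param class_label One of [structure_classes()].
#' @param mask Logical matrix; need not be tight, it is cropped.
#' @param offset Slide coordinate (x, y) of `mask[1, 1]`.
#' @param score Confidence in `[0, 1]`.
#'
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(class_label, mask, offset = c(0L, 0L), score = 1) {
  assert_structure_class(class_label)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!any(mask)) stop("instance mask must be nonempty", call. = FALSE)
  if (!is.numeric(score) || length(score) != 1L || score < 0 || score > 1) {
    stop("`score` must be a single number in [0, 1]", call. = FALSE)
  }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  mask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  x0 <- as.integer(offset[1] + cols[1] - 1L)
  y0 <- as.integer(offset[2] + rows[1] - 1L)
  structure(
    list(class_label = class_label, mask = mask,
         bbox = c(x0, y0, x0 + ncol(mask), y0 + nrow(mask)),
         score = as.numeric(score)),
    class = "instance_mask"
  )
}

#' @export
print.instance_mask <- function(x, ...) {
  b <- x$bbox
  cat(sprintf("<instance_mask> %s, bbox [%d,%d)x[%d,%d), %d px, score %.3f\n",
              x$class_label, b[1], b[3], b[2], b[4], sum(x$mask), x$score))
  invisible(x)
}

instance_area_px <- function(inst) sum(inst$mask)

instance_area_um2 <- function(inst, calib) {
  instance_area_px(inst) * pixel_area_um2(calib)
}

# paint an instance into a full-size logical raster (dim = c(h, w))
instance_to_raster <- function(inst, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  b <- inst$bbox
  out[(b[2] + 1L):b[4], (b[1] + 1L):b[3]] <- inst$mask
  out
}

# intersection of two half-open boxes, or NULL if empty
box_intersect <- function(a, b) {
  x0 <- max(a[1], b[1]); y0 <- max(a[2], b[2])
  x1 <- min(a[3], b[3]); y1 <- min(a[4], b[4])
  if (x1 <= x0 || y1 <= y0) return(NULL)
  c(x0, y0, x1, y1)
}

# crop an instance to a half-open box; NULL if the clipped mask is empty
clip_instance <- function(inst, box) {
  ib <- box_intersect(inst$bbox, box)
  if (is.null(ib)) return(NULL)
  b <- inst$bbox
  sub <- inst$mask[(ib[2] - b[2] + 1L):(ib[4] - b[2]),
                   (ib[1] - b[1] + 1L):(ib[3] - b[1]), drop = FALSE]
  if (!any(sub)) return(NULL)
  instance_mask(inst$class_label, sub, offset = ib[1:2], score = inst$score)
}

# pixel count of the mask intersection (0 when bboxes are disjoint)
instance_intersection_px <- function(a, b) {
  ib <- box_intersect(a$bbox, b$bbox)
  if (is.null(ib)) return(0L)
  sa <- a$mask[(ib[2] - a$bbox[2] + 1L):(ib[4] - a$bbox[2]),
               (ib[1] - a$bbox[1] + 1L):(ib[3] - a$bbox[1]), drop = FALSE]
  sb <- b$mask[(ib[2] - b$bbox[2] + 1L):(ib[4] - b$bbox[2]),
               (ib[1] - b$bbox[1] + 1L):(ib[3] - b$bbox[1]), drop = FALSE]
  sum(sa & sb)
}

#' Overlap between two instance masks
#'
#' @param a,b `instance_mask` objects.
#' @param criterion `"iou"` for intersection over union, `"overlap"` for
#'   intersection over the smaller mask (the fraction of the smaller
#'   instance that is shared).
#' @return A number in `[0, 1]`.
#' @export
instance_iou <- function(a, b, criterion = c("iou", "overlap")) {
  criterion <- match.arg(criterion)
  inter <- instance_intersection_px(a, b)
  if (inter == 0L) return(0)
  na <- instance_area_px(a); nb <- instance_area_px(b)
  if (criterion == "iou") inter / (na + nb - inter) else inter / min(na, nb)
}

# union of two same-class instances; score = max of parents
merge_two <- function(a, b) {
  bb <- c(min(a$bbox[1], b$bbox[1]), min(a$bbox[2], b$bbox[2]),
          max(a$bbox[3], b$bbox[3]), max(a$bbox[4], b$bbox[4]))
  m <- matrix(FALSE, bb[4] - bb[2], bb[3] - bb[1])
  for (inst in list(a, b)) {
    ib <- inst$bbox
    rows <- (ib[2] - bb[2] + 1L):(ib[4] - bb[2])
    cols <- (ib[1] - bb[1] + 1L):(ib[3] - bb[1])
    m[rows, cols] <- m[rows, cols] | inst$mask
  }
  instance_mask(a$class_label, m, offset = bb[1:2],
                score = max(a$score, b$score))
}

canonical_instance_order <- function(instances) {
  if (!length(instances)) return(integer(0))
  key <- vapply(instances, function(i) {
    sprintf("%s|%09d|%09d|%09d|%09d", i$class_label,
            i$bbox[1], i$bbox[2], i$bbox[3], i$bbox[4])
  }, character(1))
  order(key)
}

#' Merge strongly intersecting same-class instances
#'
#' A sliding-window segmenter sees large structures in several overlapping
#' windows and returns one clipped mask per window; this step reunifies
#' them. Any same-class pair whose overlap reaches `iou_min` is unioned,
#' repeatedly, until no pair qualifies (a fixpoint, so the result does not
#' depend on input order; output is canonically sorted). The merged score is
#' the max of the parents'.
#'
#' With `criterion = "overlap"` the overlap is measured against the smaller
#' mask, which is what clipping produces: a window fragment is almost
#' entirely contained in the neighbouring window's larger fragment even
#' when their IoU is well below 1/2.
#'
#' @param instances List of [instance_mask()] objects.
#' @param iou_min Merge threshold in (0, 1].
#' @param criterion See [instance_iou()].
#' @return List of merged `instance_mask` objects, canonically sorted.
#' @export
merge_instances <- function(instances, iou_min = 0.5,
                            criterion = c("iou", "overlap")) {
  criterion <- match.arg(criterion)
  if (iou_min <= 0 || iou_min > 1) {
    stop("`iou_min` must lie in (0, 1]", call. = FALSE)
  }
  cur <- instances
  repeat {
    n <- length(cur)
    if (n < 2L) break
    # union-find over pairs meeting the criterion in this round
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merged_any <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (cur[[i]]$class_label != cur[[j]]$class_label) next
        if (is.null(box_intersect(cur[[i]]$bbox, cur[[j]]$bbox))) next
        if (instance_iou(cur[[i]], cur[[j]], criterion) >= iou_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) { parent[rj] <- ri; merged_any <- TRUE }
        }
      }
    }
    if (!merged_any) break
    roots <- vapply(seq_len(n), find, integer(1))
    cur <- lapply(split(seq_len(n), roots), function(idx) {
      Reduce(merge_two, cur[idx])
    })
    names(cur) <- NULL
  }
  cur[canonical_instance_order(cur)]
}

#' Summarise a list of instances as a tibble
#'
#' @param instances List of [instance_mask()] objects.
#' @param calib Optional [pixel_calibration()] for physical areas.
#' @return A tibble with one row per instance.
#' @export
instances_tibble <- function(instances, calib = NULL) {
  if (!length(instances)) {
    return(tibble::tibble(class_label = character(0), x0 = integer(0),
                          y0 = integer(0), x1 = integer(0), y1 = integer(0),
                          area_px = integer(0), area_um2 = numeric(0),
                          score = numeric(0)))
  }
  tb <- purrr::map_dfr(instances, function(i) {
    tibble::tibble(class_label = i$class_label,
                   x0 = i$bbox[1], y0 = i$bbox[2],
                   x1 = i$bbox[3], y1 = i$bbox[4],
                   area_px = instance_area_px(i), score = i$score)
  })
  tb$area_um2 <- if (is.null(calib)) NA_real_ else tb$area_px * pixel_area_um2(calib)
  tb[, c("class_label", "x0", "y0", "x1", "y1", "area_px", "area_um2", "score")]
}
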