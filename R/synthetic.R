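# Synthetic H&E-like renal cortex with exhaustive ground truth.
#
# The generator emulates the geometry the pipeline cares about -- oval
# glomeruli (100-150 um) with a Bowman-capsule rim, a dense Voronoi packing
# of polygonal tubules (30-50 um), small arteries (>= 100 um) with a pale
# lumen, a stromal compartment whose fibrosis-eligible share is driven to a
# requested fraction, grid-aligned lymphocyte infiltrates, and rendered
# nuclei whose brightness/shape obey the same classification rules the
# detector applies. It is not a stain simulator: colours are flat with mild
# noise, and every pixel has a known class.

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic renal-cortex generator
#'
#' Defaults describe a 777 x 777 um crop of renal cortex scanned at x20
#' (0.5056 um/px): tubule, glomerulus and artery areas in the conventional
#' 40:3:2 proportion, moderate fibrosis and a clustered lymphocytic
#' infiltrate dense enough to satisfy the 2-lymphocyte / 20-cell rule in
#' every infiltrated 50 um tile, while normal stroma stays far below it.
#'
#' @param image_size_px Edge of the square image in pixels.
#' @param calibration A [pixel_calibration()].
#' @param seed RNG seed; the same seed gives byte-identical slides.
#' @param class_area_ratio Named target area ratio for tubuli, glomeruli
#'   and arteries (default `c(tubuli = 40, glomeruli = 3, arteries = 2)`).
#' @param glomerulus_diameter_um_range Glomerulus diameter range (um).
#' @param tubule_size_um_range Tubule size range (um); sets the Voronoi
#'   seed spacing.
#' @param artery_diameter_um_min Minimum artery diameter (um).
#' @param fibrosis_fraction_target Desired fibrosis-eligible stroma as a
#'   fraction of tissue, in `[0, 0.8]`.
#' @param infiltration_fraction_target Desired infiltrated fraction of
#'   tissue, in `[0, 0.6]`.
#' @param lymphocyte_density_in_infiltrate Lymphocytes per infiltrated
#'   50 x 50 um tile.
#' @param nucleus_density_in_infiltrate Additional (non-lymphocyte) nuclei
#'   per infiltrated tile; together the two defaults place 24 cells per
#'   tile, above the 20-cell rule.
#' @param nucleus_density Background nuclei per 50 x 50 um of normal
#'   stroma; the default (3) keeps normal stroma far below the rule.
#' @param proper_stroma_width_um Rim width used when computing the
#'   ground-truth fibrosis-eligible compartment; must match the pipeline
#'   configuration it is compared against.
#' @param noise_sd Gaussian pixel noise (gray levels) added at render time.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(image_size_px = 1536,
                         calibration = pixel_calibration(0.5056, "x20"),
                         seed = 1L,
                         class_area_ratio = c(tubuli = 40, glomeruli = 3,
                                              arteries = 2),
                         glomerulus_diameter_um_range = c(100, 150),
                         tubule_size_um_range = c(30, 50),
                         artery_diameter_um_min = 100,
                         fibrosis_fraction_target = 0.25,
                         infiltration_fraction_target = 0.08,
                         lymphocyte_density_in_infiltrate = 6,
                         nucleus_density_in_infiltrate = 18,
                         nucleus_density = 3,
                         proper_stroma_width_um = 15,
                         noise_sd = 2) {
  assert_calibration(calibration)
  stopifnot(image_size_px >= 256,
            all(c("tubuli", "glomeruli", "arteries") %in%
                  names(class_area_ratio)),
            diff(glomerulus_diameter_um_range) >= 0,
            diff(tubule_size_um_range) >= 0)
  if (fibrosis_fraction_target < 0 || fibrosis_fraction_target > 0.8) {
    stop("`fibrosis_fraction_target` must lie in [0, 0.8]", call. = FALSE)
  }
  if (infiltration_fraction_target < 0 || infiltration_fraction_target > 0.6) {
    stop("`infiltration_fraction_target` must lie in [0, 0.6]", call. = FALSE)
  }
  structure(
    list(image_size_px = as.integer(image_size_px),
         calibration = calibration, seed = as.integer(seed),
         class_area_ratio = class_area_ratio,
         glomerulus_diameter_um_range = glomerulus_diameter_um_range,
         tubule_size_um_range = tubule_size_um_range,
         artery_diameter_um_min = artery_diameter_um_min,
         fibrosis_fraction_target = fibrosis_fraction_target,
         infiltration_fraction_target = infiltration_fraction_target,
         lymphocyte_density_in_infiltrate = lymphocyte_density_in_infiltrate,
         nucleus_density_in_infiltrate = nucleus_density_in_infiltrate,
         nucleus_density = nucleus_density,
         proper_stroma_width_um = proper_stroma_width_um,
         noise_sd = noise_sd),
    class = "synth_params"
  )
}

# luminance on the 0-255 scale (Rec. 601 weights)
to_grayscale <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# ---- geometry helpers -------------------------------------------------------

# logical ellipse mask on the full raster; (cx, cy) 0-based px, a/b semi-axes
# in px, theta radians
ellipse_mask <- function(h, w, cx, cy, a, b, theta = 0) {
  x0 <- max(0, floor(cx - a - 2)); x1 <- min(w - 1, ceiling(cx + a + 2))
  y0 <- max(0, floor(cy - a - 2)); y1 <- min(h - 1, ceiling(cy + a + 2))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(rows = ys + 1L, cols = xs + 1L, mask = inside)
}

paint_mask <- function(target, em, value) {
  sub <- target[em$rows, em$cols]
  sub[em$mask] <- value
  target[em$rows, em$cols] <- sub
  target
}

# superellipse tissue blob with a wobbly rim
make_tissue_blob <- function(h, w) {
  xs <- (seq_len(w) - 1 - (w - 1) / 2) / (0.47 * w)
  ys <- (seq_len(h) - 1 - (h - 1) / 2) / (0.47 * h)
  r <- outer(abs(ys)^4, rep(1, w)) + outer(rep(1, h), abs(xs)^4)
  wob <- as.matrix(EBImage::gblur(matrix(stats::runif(h * w, -1, 1), h, w),
                                  sigma = min(h, w) / 24))
  r + 1.2 * wob <= 1
}

# distances to the nearest and second-nearest seed of a jittered-grid
# Voronoi diagram; returns list(d1, d2) in px
voronoi_distances <- function(h, w, spacing, jitter_frac = 0.35) {
  gx <- seq(-spacing, w + spacing, by = spacing)
  gy <- seq(-spacing, h + spacing, by = spacing)
  ngx <- length(gx); ngy <- length(gy)
  sx <- outer(rep(1, ngy), gx) + matrix(stats::runif(ngy * ngx, -1, 1), ngy) *
    jitter_frac * spacing
  sy <- outer(gy, rep(1, ngx)) + matrix(stats::runif(ngy * ngx, -1, 1), ngy) *
    jitter_frac * spacing
  px <- outer(rep(1, h), seq_len(w) - 1)
  py <- outer(seq_len(h) - 1, rep(1, w))
  ci <- pmin(pmax(floor(py / spacing) + 2L, 2L), ngy - 1L)  # row in seed grid
  cj <- pmin(pmax(floor(px / spacing) + 2L, 2L), ngx - 1L)
  d1 <- matrix(Inf, h, w); d2 <- matrix(Inf, h, w)
  for (di in -1:1) {
    for (dj in -1:1) {
      idx <- cbind(as.vector(ci + di), as.vector(cj + dj))
      d <- sqrt((as.vector(px) - sx[idx])^2 + (as.vector(py) - sy[idx])^2)
      d <- matrix(d, h, w)
      closer <- d < d1
      d2 <- pmin(d2, ifelse(closer, d1, d))
      d1 <- pmin(d1, d)
    }
  }
  list(d1 = d1, d2 = d2)
}

# place non-overlapping discs/ellipses inside `allowed` whose total area
# lands on the quota: the count comes from the mean structure size, and the
# sampled diameters are rescaled (within the anatomical range) so the
# realized class area matches the quota rather than overshooting by up to
# one structure unit. Even a small field carries at least one structure
# when its class has any quota.
place_round_structures <- function(allowed, quota_px, diam_range_px,
                                   axis_ratio_range = c(1, 1.3),
                                   max_tries = 4000) {
  h <- nrow(allowed); w <- ncol(allowed)
  ok_idx <- which(allowed)
  if (quota_px <= 0 || !length(ok_idx)) return(list())
  mean_area <- pi * (mean(diam_range_px) / 2)^2
  n <- max(1L, round(quota_px / mean_area))
  d <- stats::runif(n, diam_range_px[1], diam_range_px[2])
  d <- d * sqrt(quota_px / sum(pi * (d / 2)^2))
  d <- pmin(pmax(d, diam_range_px[1]), diam_range_px[2])
  placed <- list()
  tries <- 0
  for (i in seq_len(n)) {
    ratio <- stats::runif(1, axis_ratio_range[1], axis_ratio_range[2])
    a <- d[i] / 2 * sqrt(ratio); b <- d[i] / 2 / sqrt(ratio)
    theta <- stats::runif(1, 0, pi)
    while (tries < max_tries) {
      tries <- tries + 1
      k <- ok_idx[sample.int(length(ok_idx), 1)]
      cy <- (k - 1) %% h; cx <- (k - 1) %/% h
      # keep whole ellipse plus a margin inside `allowed`, away from others
      margin <- a + 6
      if (cx < margin || cy < margin || cx > w - 1 - margin ||
          cy > h - 1 - margin) next
      clear <- TRUE
      for (p in placed) {
        if ((cx - p$cx)^2 + (cy - p$cy)^2 < (a + p$a + 10)^2) {
          clear <- FALSE; break
        }
      }
      if (!clear) next
      em <- ellipse_mask(h, w, cx, cy, a + 4, a + 4)  # bounding disc + margin
      if (!all(allowed[em$rows, em$cols][em$mask])) next
      placed[[length(placed) + 1]] <- list(cx = cx, cy = cy, a = a, b = b,
                                           theta = theta)
      break
    }
  }
  placed
}

# ---- main generator ---------------------------------------------------------

#' Generate a synthetic renal-cortex slide with ground truth
#'
#' Builds the slide in layers: a tissue blob; glomeruli and arteries placed
#' to their share of the class area ratio; tubules as a shrunken
#' jittered-grid Voronoi packing; fibrosis carved out of the tubule packing
#' by thresholding a smooth random field, with the threshold calibrated so
#' the realized fibrosis-eligible fraction lands on the requested target;
#' infiltrates as clusters of 50 um grid tiles populated with enough
#' lymphocytes and nuclei to satisfy the density rule; and finally an
#' H&E-like rendering. Ground truth (label map, instance list, cell table,
#' realized fractions) is computed with the same geometric definitions the
#' pipeline uses, so measured-versus-true comparisons are meaningful.
#'
#' @param params A [synth_params()].
#' @return An object of class `synth_slide`: list with `rgb` (h x w x 3
#'   array, 0-255), `ground_truth` (a [label_map()]), `instances` (list of
#'   [instance_mask()]), `cells` (tibble), `true_fibrosis_pct`,
#'   `true_infiltration_pct`, `tissue_fraction_pct`, and `params`.
#' @export
generate_slide <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, build_slide(params))
}

build_slide <- function(params) {
  calib <- params$calibration
  px <- calib$pixel_size_um
  h <- w <- params$image_size_px
  um <- function(x) x / px                       # um -> px (real-valued)

  tissue <- make_tissue_blob(h, w)
  a_tissue <- sum(tissue)

  ratio <- params$class_area_ratio
  f_target <- params$fibrosis_fraction_target
  # final tubule area estimate: tissue minus the requested fibrosis, minus
  # seams and the proper stromal rim that the Voronoi packing geometry
  # turns into stroma (about half the non-fibrotic tissue at the default
  # tubule size and rim width), minus the round structures themselves
  t_est <- a_tissue * (1 - f_target) * 0.53
  quota_glom <- t_est * ratio[["glomeruli"]] / ratio[["tubuli"]]
  quota_art <- t_est * ratio[["arteries"]] / ratio[["tubuli"]]

  glom_geo <- place_round_structures(
    tissue, quota_glom, um(params$glomerulus_diameter_um_range),
    axis_ratio_range = c(1.05, 1.35))
  allowed <- tissue
  for (g in glom_geo) {
    em <- ellipse_mask(h, w, g$cx, g$cy, g$a + 14, g$a + 14)
    allowed <- paint_mask(allowed, em, FALSE)
  }
  art_geo <- place_round_structures(
    allowed, quota_art,
    um(c(params$artery_diameter_um_min, params$artery_diameter_um_min * 1.5)),
    axis_ratio_range = c(1, 1.15))

  glom_mask <- matrix(FALSE, h, w)
  for (g in glom_geo) {
    glom_mask <- paint_mask(glom_mask,
                            ellipse_mask(h, w, g$cx, g$cy, g$a, g$b, g$theta),
                            TRUE)
  }
  art_mask <- matrix(FALSE, h, w)
  for (g in art_geo) {
    art_mask <- paint_mask(art_mask,
                           ellipse_mask(h, w, g$cx, g$cy, g$a, g$b, g$theta),
                           TRUE)
  }

  # tubule candidate region: Voronoi cells shrunk by the seam half-width,
  # clipped away from round structures and the tissue rim
  spacing <- um(mean(params$tubule_size_um_range))
  vd <- voronoi_distances(h, w, spacing)
  seam_px <- um(5)
  round_margin <- um(4)
  keepout <- as.matrix(EBImage::distmap(!(glom_mask | art_mask))) > round_margin
  tubule_candidate <- tissue & keepout & (vd$d2 - vd$d1 >= seam_px)

  # carve fibrosis out of the tubule packing: threshold a smooth field so
  # that the realized fibrosis-eligible fraction matches the target
  field <- as.matrix(EBImage::gblur(matrix(stats::runif(h * w), h, w),
                                    sigma = um(30)))
  ring_px <- um(params$proper_stroma_width_um)
  min_frag_px <- um(sqrt(150)) ^ 2                 # drop fragments < 150 um^2

  realize <- function(q) {
    patch <- matrix(FALSE, h, w)
    if (q > 0) {
      cand_vals <- field[tubule_candidate]
      thr <- stats::quantile(cand_vals, min(q, 1), names = FALSE)
      patch <- tubule_candidate & (field <= thr)
    }
    tub <- tubule_candidate & !patch
    lab <- as.matrix(EBImage::bwlabel(tub))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_frag_px)
    if (length(small)) tub[matrix(lab %in% small, h, w)] <- FALSE
    structures <- glom_mask | art_mask | tub
    stroma_all <- tissue & !structures
    dstruct <- as.matrix(EBImage::distmap(!structures))
    proper <- stroma_all & (dstruct <= ring_px)
    eligible <- stroma_all & !proper
    list(q = q, tubule = tub, structures = structures,
         stroma_all = stroma_all, proper = proper, eligible = eligible,
         dstruct = dstruct,
         fib = 100 * sum(eligible) / a_tissue)
  }

  target_pct <- 100 * f_target
  state <- realize(if (f_target == 0) 0 else
    min(0.95, f_target * a_tissue / max(sum(tubule_candidate), 1)))
  if (f_target > 0) {
    lo <- NULL; hi <- NULL
    for (iter in 1:10) {
      if (abs(state$fib - target_pct) <= 1) break
      if (state$fib < target_pct) lo <- state else hi <- state
      q_next <- if (is.null(hi)) min(0.98, state$q * target_pct /
                                       max(state$fib, 1e-3))
                else if (is.null(lo)) state$q * target_pct / max(state$fib, 1e-3)
                else (lo$q + hi$q) / 2
      q_next <- max(0, min(0.98, q_next))
      state <- realize(q_next)
    }
    if (abs(state$fib - target_pct) > 3) {
      stop(sprintf(paste0("infeasible targets: realized fibrosis %.1f%% ",
                          "cannot reach target %.1f%% with the placed ",
                          "structures"), state$fib, target_pct),
           call. = FALSE)
    }
  }

  # ---- infiltration tiles ---------------------------------------------------
  tile_px <- microns_to_pixels(50, calib)
  nty <- floor(h / tile_px); ntx <- floor(w / tile_px)
  eligible <- state$eligible
  tile_elig <- matrix(0L, nty, ntx)
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      tile_elig[ty, tx] <- sum(eligible[((ty - 1) * tile_px + 1):(ty * tile_px),
                                        ((tx - 1) * tile_px + 1):(tx * tile_px)])
    }
  }
  inf_target_px <- params$infiltration_fraction_target * a_tissue
  cand <- which(tile_elig >= 0.5 * tile_px^2, arr.ind = TRUE)
  if (inf_target_px > 0 &&
      sum(tile_elig[cand]) * 0.95 < inf_target_px) {
    stop("infeasible targets: not enough fibrosis-eligible stroma to host ",
         "the requested infiltration fraction", call. = FALSE)
  }

  cells <- list()
  infiltrate_tiles <- matrix(FALSE, nty, ntx)
  inf_area_px <- 0
  d_ok <- state$dstruct                          # distance to structures
  if (inf_target_px > 0 && nrow(cand) > 0) {
    focal <- cand[sample.int(nrow(cand), 1), ]
    ordd <- order((cand[, 1] - focal[1])^2 + (cand[, 2] - focal[2])^2)
    for (k in ordd) {
      if (inf_area_px >= inf_target_px) break
      ty <- cand[k, 1]; tx <- cand[k, 2]
      placed <- place_tile_cells(
        eligible, d_ok, ty, tx, tile_px,
        n_lymph = params$lymphocyte_density_in_infiltrate,
        n_nuc = params$nucleus_density_in_infiltrate, px = px)
    if (is.null(placed)) next
      infiltrate_tiles[ty, tx] <- TRUE
      inf_area_px <- inf_area_px + tile_elig[ty, tx]
      cells <- c(cells, placed)
    }
  }

  # background nuclei in normal stroma (including the proper rim), sparse
  stroma_all <- state$stroma_all
  inf_mask <- matrix(FALSE, h, w)
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    if (infiltrate_tiles[ty, tx]) {
      inf_mask[((ty - 1) * tile_px + 1):(ty * tile_px),
               ((tx - 1) * tile_px + 1):(tx * tile_px)] <- TRUE
    }
  }
  bg_region <- stroma_all & !inf_mask
  n_bg <- round(params$nucleus_density * sum(bg_region) / tile_px^2)
  cells <- c(cells, place_background_nuclei(bg_region, d_ok, n_bg, px))

  # ---- ground-truth label map ----------------------------------------------
  codes <- matrix(0L, h, w)
  codes[state$stroma_all] <- label_code("stroma")
  codes[state$proper] <- label_code("proper_stroma")
  codes[inf_mask & eligible] <- label_code("infiltration")
  codes[state$tubule] <- label_code("tubuli")
  codes[glom_mask] <- label_code("glomeruli")
  codes[art_mask] <- label_code("arteries")
  gt <- label_map(codes, calib)

  # ---- instances ------------------------------------------------------------
  instances <- list()
  for (g in glom_geo) {
    em <- ellipse_mask(h, w, g$cx, g$cy, g$a, g$b, g$theta)
    m <- matrix(FALSE, h, w); m <- paint_mask(m, em, TRUE)
    instances <- c(instances, list(instance_mask("glomeruli", m)))
  }
  for (g in art_geo) {
    em <- ellipse_mask(h, w, g$cx, g$cy, g$a, g$b, g$theta)
    m <- matrix(FALSE, h, w); m <- paint_mask(m, em, TRUE)
    instances <- c(instances, list(instance_mask("arteries", m)))
  }
  tub_lab <- as.matrix(EBImage::bwlabel(state$tubule))
  n_tub <- max(tub_lab)
  if (n_tub > 0) {
    nz <- which(tub_lab > 0)
    vals <- tub_lab[nz]
    rows <- (nz - 1L) %% h + 1L
    cols <- (nz - 1L) %/% h + 1L
    ry0 <- tapply(rows, vals, min); ry1 <- tapply(rows, vals, max)
    rx0 <- tapply(cols, vals, min); rx1 <- tapply(cols, vals, max)
    for (i in seq_len(n_tub)) {
      sub <- tub_lab[ry0[[i]]:ry1[[i]], rx0[[i]]:rx1[[i]], drop = FALSE] == i
      instances <- c(instances, list(
        instance_mask("tubuli", sub,
                      offset = c(rx0[[i]] - 1L, ry0[[i]] - 1L))))
    }
  }
  instances <- instances[canonical_instance_order(instances)]

  cells_tb <- cells_to_tibble(cells, px)

  rgb <- render_slide(h, w, tissue, state, glom_geo, art_geo, inf_mask,
                      cells, params)

  true_fib <- 100 * sum(label_mask(gt, c("stroma", "infiltration"))) / a_tissue
  true_inf <- 100 * sum(label_mask(gt, "infiltration")) / a_tissue

  structure(
    list(rgb = rgb, ground_truth = gt, instances = instances,
         cells = cells_tb,
         true_fibrosis_pct = true_fib,
         true_infiltration_pct = true_inf,
         tissue_fraction_pct = 100 * a_tissue / (h * w),
         params = params),
    class = "synth_slide"
  )
}

# place the infiltrate cells of one tile on a jittered subgrid; NULL if the
# tile cannot host the required counts
place_tile_cells <- function(eligible, dstruct, ty, tx, tile_px,
                             n_lymph, n_nuc, px) {
  n_cells <- n_lymph + n_nuc
  k <- ceiling(sqrt(n_cells * 1.3))
  sub <- tile_px / k
  oy <- (ty - 1) * tile_px; ox <- (tx - 1) * tile_px
  slots <- expand.grid(i = seq_len(k), j = seq_len(k))
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  out <- list()
  types <- sample(c(rep("lymphocyte", n_lymph), rep("nucleus", n_nuc)))
  ti <- 1
  for (s in seq_len(nrow(slots))) {
    if (ti > n_cells) break
    cy <- oy + (slots$i[s] - 0.5) * sub + stats::runif(1, -0.2, 0.2) * sub
    cx <- ox + (slots$j[s] - 0.5) * sub + stats::runif(1, -0.2, 0.2) * sub
    cell <- draw_cell(types[ti], cx, cy, px, crowded = TRUE)
    iy <- round(cy) + 1L; ix <- round(cx) + 1L
    if (iy < 1 || ix < 1 || iy > nrow(eligible) || ix > ncol(eligible)) next
    if (!eligible[iy, ix]) next
    if (dstruct[iy, ix] <= cell$a_px + 1) next
    out[[length(out) + 1]] <- cell
    ti <- ti + 1
  }
  if (length(out) < n_cells) return(NULL)
  out
}

place_background_nuclei <- function(region, dstruct, n, px) {
  idx <- which(region)
  if (!length(idx) || n < 1) return(list())
  h <- nrow(region)
  out <- list()
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (length(out) < n && tries < 20 * n) {
    tries <- tries + 1
    k <- idx[sample.int(length(idx), 1)]
    cy <- (k - 1) %% h; cx <- (k - 1) %/% h
    if (nrow(pts) && any((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 < 24^2)) next
    cell <- draw_cell("nucleus", cx, cy, px)
    if (dstruct[cy + 1, cx + 1] <= cell$a_px + 1) next
    out[[length(out) + 1]] <- cell
    pts <- rbind(pts, c(cx, cy))
  }
  out
}

# sample one cell's geometry and brightness. Lymphocytes: near-circular
# (axis ratio <= 1.6), mean gray 50-90; nuclei: gray 100-160, round-ish in
# dense infiltrates (packed immune cells) and up to axis ratio 2.8 in
# sparse stroma (fibroblast-like). Both sides of the 95-gray / ratio-2
# classification boundary are therefore clear by construction.
draw_cell <- function(type, cx, cy, px, crowded = FALSE) {
  if (type == "lymphocyte") {
    d_um <- stats::runif(1, 6, 8)
    ratio <- stats::runif(1, 1.0, 1.6)
    gray <- stats::runif(1, 50, 90)
  } else if (crowded) {
    d_um <- stats::runif(1, 6, 8)
    ratio <- stats::runif(1, 1.1, 1.8)
    gray <- stats::runif(1, 100, 160)
  } else {
    d_um <- stats::runif(1, 6, 9)
    ratio <- stats::runif(1, 1.2, 2.8)
    gray <- stats::runif(1, 100, 160)
  }
  a_um <- d_um / 2 * sqrt(ratio); b_um <- d_um / 2 / sqrt(ratio)
  list(type = type, cx = cx, cy = cy,
       a_px = a_um / px, b_px = b_um / px,
       a_um = a_um, b_um = b_um,
       theta = stats::runif(1, 0, pi), gray = gray)
}

cells_to_tibble <- function(cells, px) {
  if (!length(cells)) {
    return(tibble::tibble(x_px = numeric(0), y_px = numeric(0),
                          x_um = numeric(0), y_um = numeric(0),
                          cell_type = character(0),
                          semi_axis_major_um = numeric(0),
                          semi_axis_minor_um = numeric(0),
                          axis_ratio = numeric(0),
                          mean_brightness = numeric(0),
                          area_um2 = numeric(0)))
  }
  purrr::map_dfr(cells, function(c) {
    tibble::tibble(x_px = c$cx, y_px = c$cy,
                   x_um = c$cx * px, y_um = c$cy * px,
                   cell_type = c$type,
                   semi_axis_major_um = c$a_um,
                   semi_axis_minor_um = c$b_um,
                   axis_ratio = c$a_um / c$b_um,
                   mean_brightness = c$gray,
                   area_um2 = pi * c$a_um * c$b_um)
  })
}

# flat H&E-ish rendering with mild noise; every colour keeps a safe margin
# from the 230-gray tissue threshold and the cell detector's dark range
render_slide <- function(h, w, tissue, state, glom_geo, art_geo, inf_mask,
                         cells, params) {
  base <- list(
    background = c(251, 249, 247),
    stroma = c(243, 216, 224),
    tubule = c(233, 178, 190),
    glom = c(219, 166, 190),
    capsule = c(240, 206, 216),
    artery = c(228, 186, 198),
    lumen = c(241, 217, 226)
  )
  ch <- lapply(1:3, function(i) matrix(base$background[i], h, w))
  set_region <- function(ch, mask, col) {
    for (i in 1:3) ch[[i]][mask] <- col[i]
    ch
  }
  ch <- set_region(ch, state$stroma_all, base$stroma)
  ch <- set_region(ch, state$tubule, base$tubule)
  for (g in glom_geo) {
    em <- ellipse_mask(h, w, g$cx, g$cy, g$a, g$b, g$theta)
    for (i in 1:3) ch[[i]] <- paint_mask(ch[[i]], em, base$capsule[i])
    em2 <- ellipse_mask(h, w, g$cx, g$cy, g$a * 0.82, g$b * 0.82, g$theta)
    for (i in 1:3) ch[[i]] <- paint_mask(ch[[i]], em2, base$glom[i])
  }
  for (g in art_geo) {
    em <- ellipse_mask(h, w, g$cx, g$cy, g$a, g$b, g$theta)
    for (i in 1:3) ch[[i]] <- paint_mask(ch[[i]], em, base$artery[i])
    em2 <- ellipse_mask(h, w, g$cx, g$cy, g$a * 0.45, g$b * 0.45, g$theta)
    for (i in 1:3) ch[[i]] <- paint_mask(ch[[i]], em2, base$lumen[i])
  }
  # cells: purple-tinted ellipses whose luminance equals the sampled gray
  tint <- c(1.05, 0.85, 1.35)
  tint <- tint / sum(tint * c(0.299, 0.587, 0.114))
  for (cl in cells) {
    em <- ellipse_mask(h, w, cl$cx, cl$cy, cl$a_px, cl$b_px, cl$theta)
    if (is.null(em)) next
    for (i in 1:3) {
      ch[[i]] <- paint_mask(ch[[i]], em, min(255, cl$gray * tint[i]))
    }
  }
  rgb <- array(0, dim = c(h, w, 3))
  for (i in 1:3) rgb[, , i] <- ch[[i]]
  if (params$noise_sd > 0) {
    rgb <- rgb + array(stats::rnorm(h * w * 3, 0, params$noise_sd),
                       dim = c(h, w, 3))
  }
  rgb[rgb < 0] <- 0; rgb[rgb > 255] <- 255
  rgb
}

#' @export
print.synth_slide <- function(x, ...) {
  d <- dim(x$ground_truth$labels)
  cat(sprintf("<synth_slide> %d x %d px, %d instances, %d cells\n",
              d[2], d[1], length(x$instances), nrow(x$cells)))
  cat(sprintf("  tissue %.1f%% of raster; fibrosis %.1f%%, infiltration %.1f%% of tissue\n",
              x$tissue_fraction_pct, x$true_fibrosis_pct,
              x$true_infiltration_pct))
  invisible(x)
}

# ---- oracle segmenter and corruption ---------------------------------------

#' Ground-truth oracle segmenter
#'
#' `oracle_segmenter()` returns the slide's ground-truth structure
#' instances clipped to a tile, each with score 1 -- a perfect segmenter
#' honouring the same contract a trained model would.
#' `make_oracle_segmenter()` wraps it as a `function(tile_rgb, calibration,
#' tile_box)` closure for [scan_slide()].
#'
#' @param slide A [generate_slide()] result.
#' @param tile_box Half-open box `c(x0, y0, x1, y1)` in slide pixels.
#' @return List of [instance_mask()] in slide coordinates.
#' @export
oracle_segmenter <- function(slide, tile_box) {
  stopifnot(inherits(slide, "synth_slide"))
  d <- dim(slide$ground_truth$labels)
  if (tile_box[1] < 0 || tile_box[2] < 0 ||
      tile_box[3] > d[2] || tile_box[4] > d[1] ||
      tile_box[3] <= tile_box[1] || tile_box[4] <= tile_box[2]) {
    stop("bounds error: tile box outside the slide", call. = FALSE)
  }
  out <- lapply(slide$instances, clip_instance, box = tile_box)
  purrr::compact(out)
}

#' @rdname oracle_segmenter
#' @export
make_oracle_segmenter <- function(slide) {
  force(slide)
  # scan_slide expects tile-local coordinates
  function(tile_rgb, calibration, tile_box) {
    lapply(oracle_segmenter(slide, tile_box), function(inst) {
      instance_mask(inst$class_label, inst$mask,
                    offset = inst$bbox[1:2] - tile_box[1:2],
                    score = inst$score)
    })
  }
}

#' Corrupt a segmentation to exercise imperfect-prediction metrics
#'
#' Each instance is dropped with probability `dropout_rate`; survivors have
#' their boundary eroded or dilated (choice and amount drawn per instance)
#' by up to `boundary_jitter_um`, and receive a random confidence score in
#' `[0.5, 1]`. Deterministic under `seed`.
#'
#' @param instances List of [instance_mask()].
#' @param dropout_rate Probability in `[0, 1]` of removing each instance.
#' @param boundary_jitter_um Maximum boundary erosion/dilation in um.
#' @param calib A [pixel_calibration()] (needed when `boundary_jitter_um > 0`).
#' @param seed RNG seed.
#' @return List of corrupted [instance_mask()].
#' @export
corrupt_segmentation <- function(instances, dropout_rate = 0,
                                 boundary_jitter_um = 0, calib = NULL,
                                 seed = 1L) {
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("`dropout_rate` must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    keep <- stats::runif(length(instances)) >= dropout_rate
    out <- list()
    for (i in seq_along(instances)) {
      if (!keep[i]) next
      inst <- instances[[i]]
      score <- stats::runif(1, 0.5, 1)
      if (boundary_jitter_um > 0) {
        jit_px <- microns_to_pixels(stats::runif(1, 0, boundary_jitter_um),
                                    assert_calibration(calib))
        grow <- stats::runif(1) < 0.5
        if (jit_px > 0) {
          pad <- jit_px + 1L
          m <- inst$mask
          big <- matrix(FALSE, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
          big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
          brush <- EBImage::makeBrush(2 * jit_px + 1, "disc")
          big <- if (grow) EBImage::dilate(big, brush) else
            EBImage::erode(big, brush)
          big <- big > 0
          if (any(big)) {
            inst <- instance_mask(inst$class_label, big,
                                  offset = inst$bbox[1:2] - pad,
                                  score = score)
          } else {
            next
          }
        } else {
          inst$score <- score
        }
      } else {
        inst$score <- score
      }
      out[[length(out) + 1]] <- inst
    }
    out
  })
}
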