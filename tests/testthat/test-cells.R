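# draw a single dark ellipse on a bright stroma patch and return the
# detection table; calibration 1 um/px keeps arithmetic transparent
detect_one <- function(a_um, b_um, gray, size = 60) {
  rgb <- flat_rgb(size, size, 225)
  cx <- size / 2; cy <- size / 2
  for (x in 1:size) {
    for (y in 1:size) {
      u <- (x - cx) / a_um; v <- (y - cy) / b_um
      if (u^2 + v^2 <= 1) rgb[y, x, ] <- gray
    }
  }
  calib <- pixel_calibration(1)
  codes <- matrix(renalmorph:::label_code("stroma"), size, size)
  lmap <- label_map(codes, calib)
  detect_cells(rgb, lmap, pipeline_config())
}

test_that("round dark cells are lymphocytes; elongated or pale ones are nuclei", {
  # axis ratio 1.2, brightness 70, ~7 um across: a lymphocyte
  lymph <- detect_one(3.8, 3.2, 70)
  expect_equal(nrow(lymph), 1)
  expect_identical(lymph$cell_type, "lymphocyte")
  expect_lt(abs(lymph$mean_brightness - 70), 3)
  expect_lt(lymph$axis_ratio, 2)
  # axis ratio ~2.5, brightness 70: too elongated for a lymphocyte
  elong <- detect_one(6.3, 2.5, 70)
  expect_equal(nrow(elong), 1)
  expect_identical(elong$cell_type, "nucleus")
  expect_gt(elong$axis_ratio, 2)
  # round but pale (brightness 120 >= 95): a nucleus
  pale <- detect_one(3.8, 3.2, 120)
  expect_equal(nrow(pale), 1)
  expect_identical(pale$cell_type, "nucleus")
})

test_that("objects outside both size gates are discarded", {
  # a 1.5 um speck is below the 4 um equivalent-diameter gate
  speck <- detect_one(0.75, 0.75, 70)
  expect_equal(nrow(speck), 0)
  # a 24 um blob exceeds the nucleus gate
  blob <- detect_one(12, 12, 70)
  expect_equal(nrow(blob), 0)
})

test_that("fitted ellipse axes recover the rendered geometry", {
  d <- detect_one(5, 2.5, 70, size = 80)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$semi_axis_major_um - 5), 0.6)
  expect_lt(abs(d$semi_axis_minor_um - 2.5), 0.4)
})

test_that("touching cells are split by the watershed", {
  size <- 60
  rgb <- flat_rgb(size, size, 225)
  for (ctr in list(c(20, 30), c(33, 30))) {   # 13 px apart, radius 7 -> touch
    for (x in 1:size) for (y in 1:size) {
      if ((x - ctr[1])^2 + (y - ctr[2])^2 <= 49) rgb[y, x, ] <- 70
    }
  }
  lmap <- label_map(matrix(renalmorph:::label_code("stroma"), size, size),
                    pixel_calibration(0.5056))
  cells <- detect_cells(rgb, lmap, pipeline_config())
  expect_equal(nrow(cells), 2)
})

test_that("cell detection on a synthetic slide recalls the rendered cells", {
  s <- test_slide(seed = 7)
  res <- test_pipeline_result(seed = 7)
  recall <- nrow(res$cells) / nrow(s$cells)
  expect_gt(recall, 0.95)
  lymph_recall <- sum(res$cells$cell_type == "lymphocyte") /
    sum(s$cells$cell_type == "lymphocyte")
  expect_gt(lymph_recall, 0.9)
})

test_that("cell detection is invariant to translating image and region", {
  s <- test_slide(seed = 13, size = 384, infiltration_fraction_target = 0.1,
                  nucleus_density = 4)
  cfg <- pipeline_config()
  calib <- s$params$calibration
  crop <- function(off) {
    rgb <- s$rgb[(1 + off):(320 + off), (1 + off):(320 + off), , drop = FALSE]
    lab <- s$ground_truth$labels[(1 + off):(320 + off), (1 + off):(320 + off)]
    # restrict to stromal labels; structures carry their own classes
    detect_cells(rgb, label_map(lab, calib), cfg)
  }
  c0 <- crop(0)
  c1 <- crop(32)
  expect_gt(nrow(c0), 0)
  # cells present in both crops must agree after shifting coordinates
  shift <- dplyr::mutate(c1, x_px = x_px + 32, y_px = y_px + 32)
  common0 <- dplyr::filter(c0, x_px > 40, x_px < 312, y_px > 40, y_px < 312)
  matched <- vapply(seq_len(nrow(common0)), function(i) {
    d2 <- (shift$x_px - common0$x_px[i])^2 + (shift$y_px - common0$y_px[i])^2
    j <- which.min(d2)
    d2[j] < 1 && shift$cell_type[j] == common0$cell_type[i]
  }, logical(1))
  expect_gt(mean(matched), 0.97)
})

test_that("tile flagging requires both lymphocyte and total-cell minima", {
  cfg <- pipeline_config()
  calib <- pixel_calibration(0.5056)
  tile_px <- microns_to_pixels(50, calib)
  codes <- matrix(renalmorph:::label_code("stroma"), tile_px, tile_px)
  lmap <- label_map(codes, calib)
  mk_cells <- function(n_lymph, n_other) {
    n <- n_lymph + n_other
    if (n == 0) return(renalmorph:::cells_empty_tibble())
    tibble::tibble(
      x_px = runif(n, 1, tile_px - 1), y_px = runif(n, 1, tile_px - 1),
      x_um = 0, y_um = 0, semi_axis_major_um = 3, semi_axis_minor_um = 3,
      axis_ratio = 1, mean_brightness = 70, area_um2 = 28,
      cell_type = c(rep("lymphocyte", n_lymph), rep("nucleus", n_other)))
  }
  flag_of <- function(n_lymph, n_other) {
    res <- map_infiltration(mk_cells(n_lymph, n_other), lmap, cfg)
    res$tiles$flagged[res$tiles$tile_x == 0 & res$tiles$tile_y == 0]
  }
  expect_true(flag_of(2, 18))     # 2 lymphocytes, 20 cells total
  expect_false(flag_of(1, 99))    # many cells, single lymphocyte
  expect_false(flag_of(19, 0))    # too few cells in total
  expect_true(flag_of(20, 0))     # 20 lymphocytes are 20 cells
  expect_false(flag_of(0, 0))     # empty tile
  # strict reading: lymphocytes do not count towards the 20 nuclei
  strict <- pipeline_config(count_lymphocytes_as_nuclei = FALSE)
  res <- map_infiltration(mk_cells(2, 18), lmap, strict)
  expect_false(res$tiles$flagged[1])
  res2 <- map_infiltration(mk_cells(2, 20), lmap, strict)
  expect_true(res2$tiles$flagged[1])
})

test_that("a flagged tile in a 100x100 um ROI yields 25% infiltration", {
  calib <- pixel_calibration(0.5056)
  tile_px <- microns_to_pixels(50, calib)        # 99 px
  n <- 2L * tile_px
  codes <- matrix(renalmorph:::label_code("stroma"), n, n)
  lmap <- label_map(codes, calib)
  cells <- tibble::tibble(
    x_px = runif(22, 1, tile_px - 1), y_px = runif(22, 1, tile_px - 1),
    x_um = 0, y_um = 0, semi_axis_major_um = 3, semi_axis_minor_um = 3,
    axis_ratio = 1, mean_brightness = 70, area_um2 = 28,
    cell_type = c(rep("lymphocyte", 2), rep("nucleus", 20)))
  res <- map_infiltration(cells, lmap, pipeline_config())
  expect_equal(sum(res$tiles$flagged), 1)
  report <- compute_morphometry(res$label_map, cells, res$tiles)
  expect_equal(report$infiltration_rel_area_pct, 25)
  expect_equal(report$fibrosis_rel_area_pct, 100)
  expect_equal(report$n_infiltration_tiles, 1L)
})

test_that("infiltration stays inside the fibrosis-eligible stroma", {
  res <- test_pipeline_result(seed = 7)
  lab <- res$label_map$labels
  expect_gte(res$report$fibrosis_rel_area_pct,
             res$report$infiltration_rel_area_pct)
  # removing lymphocytes zeroes infiltration but not fibrosis
  s <- test_slide(seed = 7)
  cells_nl <- res$cells[res$cells$cell_type != "lymphocyte", ]
  lmap0 <- derive_stroma(detect_tissue(s$rgb, 230), res$instances,
                         pipeline_config(), s$params$calibration)
  res0 <- map_infiltration(cells_nl, lmap0, pipeline_config())
  rep0 <- compute_morphometry(res0$label_map, cells_nl, res0$tiles)
  expect_equal(rep0$infiltration_rel_area_pct, 0)
  expect_equal(rep0$fibrosis_rel_area_pct, res$report$fibrosis_rel_area_pct,
               tolerance = 0.02)
})

test_that("morphometry errors on an empty label map", {
  lmap <- label_map(matrix(0L, 10, 10), x20())
  expect_error(compute_morphometry(lmap), "denominator")
})
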