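test_that("the generator is deterministic under a fixed seed", {
  p <- synth_params(image_size_px = 512, seed = 7,
                    infiltration_fraction_target = 0.05)
  s1 <- generate_slide(p)
  s2 <- generate_slide(p)
  expect_identical(s1$rgb, s2$rgb)
  expect_identical(s1$ground_truth$labels, s2$ground_truth$labels)
  expect_identical(s1$cells, s2$cells)
  s3 <- generate_slide(synth_params(image_size_px = 512, seed = 8,
                                    infiltration_fraction_target = 0.05))
  expect_false(identical(s1$rgb, s3$rgb))
  # a field too small to host the requested infiltrate is an honest error
  expect_error(generate_slide(synth_params(image_size_px = 384, seed = 7,
                                           infiltration_fraction_target = 0.3)),
               "infeasible")
})

test_that("parameter validation rejects out-of-range targets", {
  expect_error(synth_params(fibrosis_fraction_target = 0.9), "0.8")
  expect_error(synth_params(infiltration_fraction_target = 0.7), "0.6")
})

test_that("zero fibrosis target yields almost no fibrosis-eligible stroma", {
  s <- test_slide(seed = 31, size = 512, fibrosis_fraction_target = 0,
                  infiltration_fraction_target = 0)
  expect_lt(s$true_fibrosis_pct, 3)
})

test_that("realized fibrosis tracks the requested target", {
  s <- test_slide(seed = 7)         # default targets 0.25 / 0.08
  expect_lt(abs(s$true_fibrosis_pct - 25), 3)
  expect_lt(abs(s$true_infiltration_pct - 8), 3)
})

test_that("structure areas honour the 40:3:2 tubuli:glomeruli:arteries ratio", {
  s <- test_slide(seed = 11, size = 1536)
  la <- label_areas(s$ground_truth)
  area <- function(l) la$n_px[la$label == l]
  tg <- area("tubuli") / area("glomeruli")
  expect_gt(tg, 40 / 3 * 0.8)
  expect_lt(tg, 40 / 3 * 1.2)
  ga <- area("glomeruli") / area("arteries")
  expect_gt(ga, 3 / 2 * 0.7)
  expect_lt(ga, 3 / 2 * 1.3)
})

test_that("structure geometry matches renal anatomy", {
  s <- test_slide(seed = 7)
  px <- s$params$calibration$pixel_size_um
  glom <- purrr::keep(s$instances, ~ .x$class_label == "glomeruli")
  expect_gte(length(glom), 1)
  for (g in glom) {
    extent_um <- max(g$bbox[3] - g$bbox[1], g$bbox[4] - g$bbox[2]) * px
    expect_gt(extent_um, 90); expect_lt(extent_um, 170)
  }
  art <- purrr::keep(s$instances, ~ .x$class_label == "arteries")
  for (a in art) {
    extent_um <- max(a$bbox[3] - a$bbox[1], a$bbox[4] - a$bbox[2]) * px
    expect_gt(extent_um, 90)
  }
  tub <- purrr::keep(s$instances, ~ .x$class_label == "tubuli")
  expect_gt(length(tub), 20)
})

test_that("rendered lymphocytes satisfy the detection rules by construction", {
  s <- test_slide(seed = 7)
  lymph <- s$cells[s$cells$cell_type == "lymphocyte", ]
  expect_gt(nrow(lymph), 5)
  expect_true(all(lymph$axis_ratio < 2))
  expect_true(all(lymph$mean_brightness < 95))
  nuc <- s$cells[s$cells$cell_type == "nucleus", ]
  expect_true(all(nuc$mean_brightness >= 95))
})

test_that("every rendered cell lies in stromal ground truth", {
  s <- test_slide(seed = 7)
  lab <- s$ground_truth$labels
  at <- lab[cbind(round(s$cells$y_px) + 1L, round(s$cells$x_px) + 1L)]
  expect_true(all(class_labels()[at + 1L] %in%
                    c("stroma", "proper_stroma", "infiltration")))
})

test_that("true percentages agree with area_fraction on the label map", {
  s <- test_slide(seed = 7)
  gt <- s$ground_truth
  tissue <- gt$labels != 0L
  fib <- matrix(gt$labels %in% renalmorph:::label_code(c("stroma", "infiltration")),
                nrow = nrow(gt$labels))
  expect_equal(s$true_fibrosis_pct, area_fraction(fib, tissue))
})

test_that("the oracle segmenter clips ground truth exactly", {
  s <- test_slide(seed = 7, size = 512,
                  infiltration_fraction_target = 0.05)
  d <- dim(s$ground_truth$labels)
  full <- oracle_segmenter(s, c(0, 0, d[2], d[1]))
  expect_length(full, length(s$instances))
  expect_equal(sum(purrr::map_int(full, renalmorph:::instance_area_px)),
               sum(purrr::map_int(s$instances, renalmorph:::instance_area_px)))
  # a tile bisecting one glomerulus returns the ground-truth intersection
  g <- purrr::detect(s$instances, ~ .x$class_label == "glomeruli")
  mid_x <- (g$bbox[1] + g$bbox[3]) %/% 2
  tile <- c(g$bbox[1] - 2, g$bbox[2] - 2, mid_x, g$bbox[4] + 2)
  got <- oracle_segmenter(s, tile)
  gg <- purrr::detect(got, ~ .x$class_label == "glomeruli")
  manual <- renalmorph:::clip_instance(g, tile)
  expect_identical(gg$mask, manual$mask)
  expect_identical(gg$bbox, manual$bbox)
  # out-of-bounds tiles are rejected
  expect_error(oracle_segmenter(s, c(-1, 0, 10, 10)), "bounds")
  expect_error(oracle_segmenter(s, c(0, 0, d[2] + 1, 5)), "bounds")
})

test_that("a tile of pure stroma contains no instances", {
  s <- test_slide(seed = 7, size = 512, infiltration_fraction_target = 0.05)
  lab <- s$ground_truth$labels
  stroma_codes <- renalmorph:::label_code(c("stroma", "proper_stroma",
                                            "infiltration"))
  found <- FALSE
  for (y0 in seq(0, nrow(lab) - 16, by = 16)) {
    for (x0 in seq(0, ncol(lab) - 16, by = 16)) {
      block <- lab[(y0 + 1):(y0 + 16), (x0 + 1):(x0 + 16)]
      if (all(block %in% stroma_codes)) {
        expect_length(oracle_segmenter(s, c(x0, y0, x0 + 16, y0 + 16)), 0)
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("segmentation corruption is seed-reproducible and boundary-true", {
  s <- test_slide(seed = 7, size = 512, infiltration_fraction_target = 0.05)
  insts <- s$instances
  # no corruption: identical geometry
  same <- corrupt_segmentation(insts, dropout_rate = 0,
                               boundary_jitter_um = 0, seed = 4)
  expect_equal(lapply(same, `[[`, "mask"), lapply(insts, `[[`, "mask"))
  # total dropout: nothing left
  expect_length(corrupt_segmentation(insts, dropout_rate = 1, seed = 4), 0)
  # seeded half dropout replays exactly
  c1 <- corrupt_segmentation(insts, dropout_rate = 0.5, seed = 9)
  c2 <- corrupt_segmentation(insts, dropout_rate = 0.5, seed = 9)
  expect_identical(lapply(c1, `[[`, "bbox"), lapply(c2, `[[`, "bbox"))
  expect_identical(length(c1),
                   sum(renalmorph:::with_seed(9, stats::runif(length(insts))) >= 0.5))
  # jitter changes boundaries but keeps the instance roughly in place
  j <- corrupt_segmentation(insts, dropout_rate = 0, boundary_jitter_um = 3,
                            calib = x20(), seed = 2)
  expect_length(j, length(insts))
})
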