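test_that("dice score follows 2TP/(2TP+FN+FP)", {
  expect_equal(dice_score(2, 1, 1), 2 / 3, tolerance = 1e-4)
  m <- matrix(runif(100) < 0.5, 10, 10)
  expect_equal(dice_from_masks(m, m), 1)
  expect_equal(dice_from_masks(m, !m), 0)
  both_empty <- dice_from_masks(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))
  expect_equal(as.numeric(both_empty), 1)
  expect_true(attr(both_empty, "degenerate"))
  expect_error(dice_from_masks(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "alignment")
})

test_that("dice equals 2|A.B| / (|A|+|B|) on random mask pairs", {
  set.seed(5)
  for (i in 1:100) {
    a <- matrix(runif(144) < runif(1, 0.2, 0.8), 12, 12)
    b <- matrix(runif(144) < runif(1, 0.2, 0.8), 12, 12)
    if (!any(a) && !any(b)) next
    expect_equal(as.numeric(dice_from_masks(a, b)),
                 2 * sum(a & b) / (sum(a) + sum(b)))
  }
})

test_that("dice bands split at 0.6 and 0.8", {
  expect_identical(dice_band(c(0.95, 0.8, 0.7, 0.6, 0.59)),
                   c("good", "acceptable", "acceptable", "acceptable", "bad"))
})

test_that("confusion matrix is column-normalized over actual classes", {
  cl <- c("glomeruli", "tubuli")
  truth <- matrix(c("glomeruli", "glomeruli", "glomeruli", "tubuli"), 2, 2)
  pred <- matrix(c("glomeruli", "glomeruli", "tubuli", "tubuli"), 2, 2)
  cm <- confusion_matrix(pred, truth, classes = cl)
  expect_equal(cm["glomeruli", "glomeruli"], 2 / 3, tolerance = 1e-3)
  expect_equal(cm["tubuli", "glomeruli"], 1 / 3, tolerance = 1e-3)
  expect_equal(colSums(cm), c(glomeruli = 1, tubuli = 1))
  raw <- confusion_matrix(pred, truth, classes = cl, normalize = FALSE)
  expect_equal(sum(raw), 4)
  # perfect prediction gives the identity after normalization
  eye <- confusion_matrix(truth, truth, classes = cl)
  expect_equal(unname(eye), diag(2))
  # total confusion: column A all lands in row B
  allb <- matrix("tubuli", 2, 2)
  cm2 <- confusion_matrix(allb, matrix("glomeruli", 2, 2), classes = cl)
  expect_equal(cm2["tubuli", "glomeruli"], 1)
})

test_that("average precision handles the canonical matching cases", {
  t1 <- square_instance("glomeruli", 5, 5, 10)
  # identical prediction: perfect AP at every threshold
  ap <- average_precision(list(t1), list(t1))
  expect_equal(attr(ap, "class_ap"), 1)
  expect_equal(nrow(ap), 10)
  # no predictions at all
  expect_equal(attr(average_precision(list(), list(t1)), "class_ap"), 0)
  # predictions against empty truth
  expect_equal(attr(average_precision(list(t1), list()), "class_ap"), 0)
  # both empty: undefined
  expect_true(is.na(attr(average_precision(list(), list()), "class_ap")))
})

test_that("a single IoU-0.7 match scores AP 0.5 over the ten COCO thresholds", {
  truth <- instance_mask("glomeruli", {
    m <- matrix(FALSE, 40, 40); m[1:10, 1:20] <- TRUE; m
  })
  pred <- instance_mask("glomeruli", {
    m <- matrix(FALSE, 40, 40); m[1:10, 4:23] <- TRUE; m
  }, score = 0.9)
  expect_equal(instance_iou(pred, truth), 170 / 230, tolerance = 1e-9)
  ap <- average_precision(list(pred), list(truth))
  expect_equal(ap$ap, c(rep(1, 5), rep(0, 5)))  # matches at 0.50..0.70 only
  expect_equal(attr(ap, "class_ap"), 0.5)
})

test_that("mAP averages defined class APs and flags undefined classes", {
  g <- square_instance("glomeruli", 0, 0, 10)
  t <- square_instance("tubuli", 20, 20, 8)
  res <- mean_average_precision(list(g, t), list(g, t))
  expect_equal(res$map, 1)
  expect_equal(res$n_classes, 2)     # arteries absent on both sides
  expect_true(is.na(res$per_class$ap[res$per_class$class_label == "arteries"]))
  # dropping one class's predictions halves nothing but its own AP
  res2 <- mean_average_precision(list(g), list(g, t))
  expect_equal(res2$per_class$ap[res2$per_class$class_label == "glomeruli"], 1)
  expect_equal(res2$per_class$ap[res2$per_class$class_label == "tubuli"], 0)
  expect_equal(res2$map, 0.5)
})

test_that("greedy matching consumes each truth at most once", {
  truth <- square_instance("glomeruli", 0, 0, 10)
  dup1 <- instance_mask("glomeruli", matrix(TRUE, 10, 10), score = 0.9)
  dup2 <- instance_mask("glomeruli", matrix(TRUE, 10, 10), score = 0.8)
  ap <- average_precision(list(dup1, dup2), list(truth))
  # precision falls to 1/2 at the duplicate; all-point AP stays 1 at each
  # threshold because recall 1 is reached at precision 1 first
  expect_equal(attr(ap, "class_ap"), 1)
  # reversed: the duplicate outranks the match -> AP 0.5 at every threshold
  off <- instance_mask("glomeruli", matrix(TRUE, 10, 10),
                       offset = c(30, 30), score = 0.95)
  ap2 <- average_precision(list(off, dup2), list(truth))
  expect_equal(attr(ap2, "class_ap"), 0.5)
})
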