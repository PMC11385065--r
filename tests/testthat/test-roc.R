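mk_records <- function(pos, neg, feature = "infiltration") {
  col <- renalmorph:::feature_column(feature)
  tb <- tibble::tibble(
    slide_id = sprintf("S%03d", seq_len(length(pos) + length(neg))),
    infiltration_rel_area_pct = 0, fibrosis_rel_area_pct = 0,
    ci_score = c(rep(2L, length(pos)), rep(0L, length(neg))),
    i_score = c(rep(2L, length(pos)), rep(0L, length(neg))))
  tb[[col]] <- c(pos, neg)
  tb
}

test_that("perfect separation gives AUC 1 with sens = spec = 100%", {
  r <- roc_analysis(mk_records(c(30, 40, 50), c(1, 2, 3)), "infiltration", "ci")
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  expect_equal(r$youden_j_max, 1)
  expect_true(r$optimal_cutoff > 3 && r$optimal_cutoff <= 30)
})

test_that("identical feature values give AUC 0.5", {
  r <- roc_analysis(mk_records(c(7, 7, 7), c(7, 7, 7)), "infiltration", "ci")
  expect_equal(r$auc, 0.5)
})

test_that("a hand-counted cohort gives AUC 8/9", {
  # positives {10,12,14}, negatives {1,2,11}: 8 of 9 pairs concordant
  r <- roc_analysis(mk_records(c(10, 12, 14), c(1, 2, 11)))
  expect_equal(r$auc, 8 / 9)
})

test_that("one-class cohorts are rejected", {
  tb <- mk_records(c(10, 12), numeric(0))
  expect_error(roc_analysis(tb), "degenerate")
})

test_that("trapezoidal AUC equals the concordant-pair fraction", {
  set.seed(17)
  for (i in 1:100) {
    n_pos <- sample(3:12, 1); n_neg <- sample(3:12, 1)
    pos <- round(runif(n_pos, 0, 20), 1)
    neg <- round(runif(n_neg, 0, 20), 1)
    r <- roc_analysis(mk_records(pos, neg))
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-10)
  }
})

test_that("ROC analysis agrees with pROC on a random cohort", {
  set.seed(23)
  pos <- rnorm(40, 12, 4); neg <- rnorm(50, 6, 4)
  pos <- pmax(pos, 0); neg <- pmax(neg, 0)
  r <- roc_analysis(mk_records(pos, neg))
  ref <- pROC::roc(response = c(rep(1, 40), rep(0, 50)),
                   predictor = c(pos, neg), quiet = TRUE,
                   direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  best <- pROC::coords(ref, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
  expect_equal(r$sens_at_cutoff + r$spec_at_cutoff,
               best$sensitivity + best$specificity, tolerance = 1e-10)
})

test_that("ROC is invariant under strictly monotone feature transforms", {
  set.seed(29)
  pos <- runif(20, 5, 30); neg <- runif(25, 0, 15)
  r1 <- roc_analysis(mk_records(pos, neg))
  r2 <- roc_analysis(mk_records(sqrt(pos) * 10, sqrt(neg) * 10))
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$youden_j_max, r2$youden_j_max)
  expect_equal(r1$sens_at_cutoff, r2$sens_at_cutoff)
})

test_that("score-group prediction uses the >= cutoff convention", {
  pred <- predict_score_group(c(4.9, 5, 5.1, 0), cutoff = 5)
  expect_identical(as.character(pred), c("low", "high", "high", "low"))
})

test_that("noise-free label assignment drives AUC to 1", {
  # labels assigned by thresholding the true area: decreasing noise makes
  # the measured-area ROC approach perfect discrimination
  set.seed(31)
  true_area <- runif(120, 0, 30)
  score <- ifelse(true_area >= 12, 2L, 0L)
  aucs <- vapply(c(6, 2, 0), function(noise) {
    measured <- pmax(true_area + rnorm(120, 0, noise), 0)
    tb <- tibble::tibble(slide_id = as.character(1:120),
                         infiltration_rel_area_pct = measured,
                         fibrosis_rel_area_pct = 0,
                         ci_score = score, i_score = score)
    roc_analysis(tb, "infiltration", "ci")$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_equal(aucs[3], 1)
})

test_that("tidy/glance/autoplot expose the ROC result", {
  r <- roc_analysis(mk_records(c(10, 12, 14), c(1, 2, 11)))
  td <- tidy(r)
  expect_true(all(c("cutoff", "sensitivity", "specificity") %in% names(td)))
  expect_equal(nrow(td), length(unique(c(10, 12, 14, 1, 2, 11))) + 1)
  gl <- glance(r)
  expect_equal(gl$auc, 8 / 9)
  expect_equal(gl$n_pos, 3)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("spearman correlation matches the rank formula", {
  expect_equal(spearman_correlation(1:10, (1:10)^3), 1)
  expect_equal(spearman_correlation(1:10, -(1:10)^3), -1)
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(spearman_correlation(1:5, rep(2, 5)), "constant")
  expect_error(spearman_correlation(1:4, 1:5), "equal length")
})

test_that("binormal cohorts reproduce the closed-form AUC", {
  coh <- simulate_score_cohort(n_per_group = 200, d_prime = 2, seed = 5)
  expect_equal(nrow(coh), 400)
  r <- roc_analysis(coh, "infiltration", "ci")
  expect_lt(abs(r$auc - pnorm(2 / sqrt(2))), 0.03)
  # determinism
  coh2 <- simulate_score_cohort(n_per_group = 200, d_prime = 2, seed = 5)
  expect_identical(coh, coh2)
})

test_that("slide records survive a CSV round trip and are validated", {
  coh <- simulate_score_cohort(n_per_group = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_slide_records(coh, path)
  back <- read_slide_records(path)
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12)
  bad <- coh; bad$ci_score[1] <- 7L
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_slide_records(bad, path2)
  expect_error(read_slide_records(path2), "ci_score")
})
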