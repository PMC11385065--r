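# Discrimination of Banff score groups from per-slide morphometry.
#
# Slides scored 0-1 form the negative group and 2-3 the positive group;
# the measured relative area (infiltration or fibrosis, in % of tissue) is
# the classifier. The ROC curve is swept over every distinct feature value
# with the convention "value >= cutoff is positive".

feature_column <- function(feature = c("infiltration", "fibrosis")) {
  switch(match.arg(feature),
         infiltration = "infiltration_rel_area_pct",
         fibrosis = "fibrosis_rel_area_pct")
}

score_column <- function(score = c("ci", "i")) {
  paste0(match.arg(score), "_score")
}

#' ROC analysis of a morphometric feature against Banff score groups
#'
#' Dichotomizes the chosen Banff score at 0-1 versus 2-3, sweeps every
#' distinct feature value as a cutoff (plus an all-negative endpoint),
#' computes the empirical ROC curve and its trapezoidal AUC (equal to the
#' Mann-Whitney concordant-pair fraction with ties counted one half), and
#' reports the Youden-optimal cutoff with its sensitivity and specificity.
#'
#' @param records Data frame of per-slide records with columns
#'   `infiltration_rel_area_pct`, `fibrosis_rel_area_pct`, `ci_score`,
#'   `i_score` (see [simulate_score_cohort()] for the layout).
#' @param feature `"infiltration"` or `"fibrosis"`.
#' @param score `"ci"` or `"i"`.
#' @return An object of class `roc_result`; see [tidy.roc_result()] and
#'   [glance.roc_result()].
#' @export
roc_analysis <- function(records, feature = c("infiltration", "fibrosis"),
                         score = c("ci", "i")) {
  feature <- match.arg(feature); score <- match.arg(score)
  fcol <- feature_column(feature); scol <- score_column(score)
  for (col in c(fcol, scol)) {
    if (!col %in% names(records)) {
      stop("records are missing column `", col, "`", call. = FALSE)
    }
  }
  s <- records[[scol]]
  if (any(!s %in% 0:3)) {
    stop("scores must lie in 0..3", call. = FALSE)
  }
  value <- records[[fcol]]
  positive <- s >= 2
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate labels: both score groups (0-1 and 2-3) must be ",
         "present", call. = FALSE)
  }
  cutoffs <- c(sort(unique(value)), Inf)
  sens <- vapply(cutoffs, function(t) sum(value >= t & positive) / n_pos,
                 numeric(1))
  spec <- vapply(cutoffs, function(t) sum(value < t & !positive) / n_neg,
                 numeric(1))
  fpr <- 1 - spec
  # the cutoff sweep spans (0,0) (cutoff +Inf) to (1,1) (cutoff = min value)
  ord <- order(fpr, sens)
  fx <- fpr[ord]; fy <- sens[ord]
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  j <- sens + spec - 1
  best <- order(-j, -sens, cutoffs)[1]
  structure(
    list(feature = feature, score = score,
         n_pos = n_pos, n_neg = n_neg,
         curve = tibble::tibble(cutoff = cutoffs, sensitivity = sens,
                                specificity = spec, fpr = fpr,
                                youden_j = j),
         auc = auc,
         youden_j_max = j[best],
         optimal_cutoff = cutoffs[best],
         sens_at_cutoff = sens[best],
         spec_at_cutoff = spec[best]),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s area vs %s score (0-1 vs 2-3)\n",
              x$feature, x$score))
  cat(sprintf("  n = %d positive / %d negative\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC = %.4f\n", x$auc))
  cat(sprintf("  Youden-optimal cutoff = %.3f%%: sensitivity %.1f%%, specificity %.1f%%, J = %.3f\n",
              x$optimal_cutoff, 100 * x$sens_at_cutoff,
              100 * x$spec_at_cutoff, x$youden_j_max))
  invisible(x)
}

#' Tidy the ROC curve of a `roc_result`
#'
#' @param x A [roc_analysis()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-cutoff curve tibble. `glance()`: a one-row
#'   summary (auc, youden_j_max, optimal_cutoff, sens/spec at cutoff,
#'   group sizes).
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(feature = x$feature, score = x$score,
                 n_pos = x$n_pos, n_neg = x$n_neg, auc = x$auc,
                 youden_j_max = x$youden_j_max,
                 optimal_cutoff = x$optimal_cutoff,
                 sens_at_cutoff = x$sens_at_cutoff,
                 spec_at_cutoff = x$spec_at_cutoff)
}

#' @rdname tidy.roc_result
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve[order(object$curve$fpr, object$curve$sensitivity), ]
  opt <- object$curve[which(object$curve$cutoff == object$optimal_cutoff), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("%s area vs %s score: AUC = %.3f",
                      object$feature, object$score, object$auc),
      subtitle = sprintf("Youden-optimal cutoff %.2f%% (sens %.1f%%, spec %.1f%%)",
                         object$optimal_cutoff, 100 * object$sens_at_cutoff,
                         100 * object$spec_at_cutoff)) +
    ggplot2::theme_minimal()
}

#' Predict the Banff score group from a measured area
#'
#' @param value Measured relative area(s), in percent.
#' @param cutoff Cutoff from [roc_analysis()] (feature units, %). A value
#'   equal to the cutoff is classified high.
#' @return Factor with levels `low` (scores 0-1) and `high` (scores 2-3).
#' @export
predict_score_group <- function(value, cutoff) {
  factor(ifelse(value >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (tie-aware), as used to
#' relate measured infiltration and fibrosis areas.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Simulate a binormal cohort of scored slides
#'
#' Generates per-slide records in which the low score group (0-1) draws
#' its measured areas from `N(mu0, sd)` and the high group (2-3) from
#' `N(mu0 + d_prime * sd, sd)`, clamped to `[0, 100]`. Under the binormal
#' model the expected AUC is `pnorm(d_prime / sqrt(2))`; at the default
#' `d_prime = 2` that is 0.921.
#'
#' @param n_per_group Slides per group.
#' @param d_prime Standardized group separation.
#' @param mu0 Mean of the low group (%).
#' @param sd Common standard deviation (%).
#' @param seed RNG seed.
#' @return Tibble with `slide_id`, `infiltration_rel_area_pct`,
#'   `fibrosis_rel_area_pct`, `ci_score`, `i_score`.
#' @export
simulate_score_cohort <- function(n_per_group = 200, d_prime = 2,
                                  mu0 = 8, sd = 5, seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_group
    grp <- rep(c(0L, 1L), each = n_per_group)
    mu <- mu0 + grp * d_prime * sd
    inf <- pmin(pmax(stats::rnorm(n, mu, sd), 0), 100)
    fib <- pmin(pmax(stats::rnorm(n, mu * 2, sd * 1.5), 0), 100)
    score <- ifelse(grp == 0L, sample(0:1, n, replace = TRUE),
                    sample(2:3, n, replace = TRUE, prob = c(0.8, 0.2)))
    tibble::tibble(
      slide_id = sprintf("S%04d", seq_len(n)),
      infiltration_rel_area_pct = inf,
      fibrosis_rel_area_pct = fib,
      ci_score = as.integer(score),
      i_score = as.integer(score)
    )
  })
}

#' Read / write per-slide morphometry records
#'
#' CSV with the documented header `slide_id, infiltration_rel_area_pct,
#' fibrosis_rel_area_pct, ci_score, i_score`.
#'
#' @param path File path.
#' @return A validated tibble of slide records.
#' @export
read_slide_records <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("slide_id", "infiltration_rel_area_pct",
                "fibrosis_rel_area_pct", "ci_score", "i_score")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop("slide record CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("ci_score", "i_score")) {
    if (any(!tb[[col]] %in% 0:3)) {
      stop("column `", col, "` must contain scores 0..3", call. = FALSE)
    }
  }
  for (col in c("infiltration_rel_area_pct", "fibrosis_rel_area_pct")) {
    if (any(tb[[col]] < 0 | tb[[col]] > 100)) {
      stop("column `", col, "` must lie in [0, 100]", call. = FALSE)
    }
  }
  tb
}

#' @rdname read_slide_records
#' @param records Tibble of slide records.
#' @export
write_slide_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
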