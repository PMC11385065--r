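# Shared fixtures, generated in code and cached for the duration of one
# test run. Small synthetic slides (768 px ~ 388 um at x20) are enough to
# exercise every pipeline stage and keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

x20 <- function() pixel_calibration(0.5056, "x20")

test_slide <- function(seed = 7, size = 768, ...) {
  extra <- list(...)
  key <- paste0("slide_", seed, "_", size,
                if (length(extra)) paste0("_", paste(names(extra), unlist(extra),
                                                     sep = "=", collapse = "_")))
  cached(key, generate_slide(do.call(synth_params, c(
    list(image_size_px = size, seed = seed), extra))))
}

test_pipeline_result <- function(seed = 7, size = 768) {
  key <- paste0("pipe_", seed, "_", size)
  cached(key, {
    s <- test_slide(seed, size)
    run_full_pipeline(s$rgb, make_oracle_segmenter(s),
                      s$params$calibration, pipeline_config())
  })
}

# square instance helper: a filled square of side `side` px at (x0, y0)
square_instance <- function(class_label, x0, y0, side, score = 1) {
  instance_mask(class_label, matrix(TRUE, side, side),
                offset = c(x0, y0), score = score)
}

# random blob instance within an n x n canvas (for property tests)
random_instance <- function(n = 32, class_label = "tubuli", score = NULL) {
  cx <- runif(1, 6, n - 6); cy <- runif(1, 6, n - 6)
  r <- runif(1, 2, 6)
  xs <- matrix(rep(1:n, each = n), n) - 0.5
  ys <- matrix(rep(1:n, n), n) - 0.5
  m <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  if (!any(m)) m[round(cy), round(cx)] <- TRUE
  instance_mask(class_label, m, score = if (is.null(score)) runif(1) else score)
}

# flat gray test image (h x w x 3)
flat_rgb <- function(h, w, value) {
  array(value, dim = c(h, w, 3))
}
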