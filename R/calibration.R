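#' Pixel calibration for a whole-slide image
#'
#' A calibration ties pixel coordinates to physical distances. Scanners
#' report the physical edge length of one pixel in micrometers; at x20
#' magnification a typical value is 0.5056 um/px, at x40 about 0.2519 um/px.
#'
#' @param pixel_size_um Physical edge length of one pixel in micrometers.
#'   Must be a single positive finite number.
#' @param magnification Free-text magnification tag, e.g. `"x20"`. Optional.
#'
#' @return An object of class `pixel_calibration`.
#' @examples
#' calib <- pixel_calibration(0.5056, "x20")
#' microns_to_pixels(50, calib)
#' @export
pixel_calibration <- function(pixel_size_um, magnification = NA_character_) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("calibration error: `pixel_size_um` must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(pixel_size_um = as.numeric(pixel_size_um),
         magnification = as.character(magnification)),
    class = "pixel_calibration"
  )
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %.4f um/px (%s)\n",
              x$pixel_size_um,
              if (is.na(x$magnification)) "unlabelled" else x$magnification))
  invisible(x)
}

is_calibration <- function(x) inherits(x, "pixel_calibration")

assert_calibration <- function(calib) {
  if (!is_calibration(calib)) {
    stop("calibration error: a `pixel_calibration` object is required",
         call. = FALSE)
  }
  calib
}

#' Convert a physical length to a pixel count
#'
#' Lengths are rounded half-away-from-zero so that a 50 um window at
#' 0.5056 um/px (x20) maps to 99 px: 50 / 0.5056 = 98.89, rounded up.
#' Base R's `round()` rounds half to even and is not used here.
#'
#' @param length_um Physical length in micrometers, `>= 0`. Vectorised.
#' @param calib A [pixel_calibration()].
#'
#' @return Integer pixel count(s).
#' @examples
#' microns_to_pixels(50, pixel_calibration(0.5056))  # 99
#' microns_to_pixels(50, pixel_calibration(0.2519))  # 198
#' @export
microns_to_pixels <- function(length_um, calib) {
  assert_calibration(calib)
  if (any(!is.finite(length_um)) || any(length_um < 0)) {
    stop("`length_um` must be finite and >= 0", call. = FALSE)
  }
  as.integer(floor(length_um / calib$pixel_size_um + 0.5))
}

#' Convert a pixel count back to micrometers
#'
#' @param n_px Pixel count(s).
#' @param calib A [pixel_calibration()].
#' @return Length(s) in micrometers.
#' @export
pixels_to_microns <- function(n_px, calib) {
  assert_calibration(calib)
  n_px * calib$pixel_size_um
}

# area of one pixel in um^2
pixel_area_um2 <- function(calib) calib$pixel_size_um^2

#' Relative area of one mask within another
#'
#' The relative-area primitive behind every "% of tissue" figure the
#' pipeline reports: `100 * |mask_a| / |mask_total|`. `mask_a` must be
#' contained in `mask_total`.
#'
#' @param mask_a Logical matrix (the part).
#' @param mask_total Logical matrix (the whole); same shape, nonempty.
#'
#' @return Percentage in `[0, 100]`.
#' @examples
#' total <- matrix(TRUE, 10, 20)
#' part <- total & FALSE; part[1:5, 1:5] <- TRUE
#' area_fraction(part, total)  # 12.5
#' @export
area_fraction <- function(mask_a, mask_total) {
  if (!identical(dim(mask_a), dim(mask_total))) {
    stop("masks must have identical shape", call. = FALSE)
  }
  a <- as.logical(mask_a)
  t <- as.logical(mask_total)
  n_total <- sum(t)
  if (n_total == 0L) {
    stop("undefined denominator: `mask_total` is empty", call. = FALSE)
  }
  if (any(a & !t)) {
    stop("containment error: `mask_a` has pixels outside `mask_total`",
         call. = FALSE)
  }
  100 * sum(a) / n_total
}
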