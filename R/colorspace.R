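# sRGB (IEC 61966-2-1, D65 white, 2 degree observer) <-> CIE L*a*b*.
# Implemented directly from the standard closed forms so that the generator's
# truth, the feature extractor and any external tool agree on units.

# sRGB linear RGB -> XYZ matrix (D65), and its inverse
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)
.white_d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

.as_pixel_matrix <- function(image) {
  if (is.null(dim(image)) && length(image) == 3L) {
    dim(image) <- c(1L, 1L, 3L)
  }
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  }
  matrix(image, nrow = prod(d[1:2]), ncol = 3L)
}

#' Convert an 8-bit sRGB image to CIE L*a*b*
#'
#' Applies the standard sRGB transfer function, the D65 RGB-to-XYZ matrix and
#' the CIE L*a*b* forward transform per pixel. Inputs may be integers in
#' `[0, 255]` or doubles in `[0, 1]`; the scale is inferred from the maximum
#' unless `max_value` is given.
#'
#' @param image An `H x W x 3` array (or a length-3 vector for one pixel).
#' @param max_value Scalar input white level, `255` or `1`. Default guesses
#'   from the data: values above 1 imply a 0-255 coding.
#' @return An array of the same spatial size with channels L* in `[0, 100]`,
#'   a* and b* roughly in `[-128, 127]`.
#' @examples
#' rgb_to_lab(c(255, 255, 0)) # strong yellow: high L*, negative a*, large b*
#' @seealso [lab_to_rgb()]
#' @export
rgb_to_lab <- function(image, max_value = NULL) {
  px <- .as_pixel_matrix(image)
  if (is.null(max_value)) {
    max_value <- if (max(px, 0) > 1) 255 else 1
  }
  lin <- .srgb_decode(px / max_value)
  xyz <- lin %*% t(.rgb2xyz)
  fx <- .lab_f(sweep(xyz, 2L, .white_d65, "/"))
  lab <- cbind(
    116 * fx[, 2L] - 16,
    500 * (fx[, 1L] - fx[, 2L]),
    200 * (fx[, 2L] - fx[, 3L])
  )
  out <- array(lab, dim = if (is.null(dim(image))) c(1L, 1L, 3L) else dim(image))
  if (is.null(dim(image))) c(out) else out
}

#' Convert CIE L*a*b* to sRGB
#'
#' Inverse of [rgb_to_lab()]. Out-of-gamut values are clipped into `[0, 1]`
#' before gamma encoding.
#'
#' @param lab An `H x W x 3` L*a*b* array (or a length-3 vector).
#' @param max_value Output white level; `1` (default) for doubles in
#'   `[0, 1]`, `255` for 8-bit-scaled doubles.
#' @return sRGB array of the same spatial size.
#' @export
lab_to_rgb <- function(lab, max_value = 1) {
  px <- .as_pixel_matrix(lab)
  fy <- (px[, 1L] + 16) / 116
  fx <- fy + px[, 2L] / 500
  fz <- fy - px[, 3L] / 200
  xyz <- cbind(.lab_finv(fx), .lab_finv(fy), .lab_finv(fz))
  xyz <- sweep(xyz, 2L, .white_d65, "*")
  rgb <- .srgb_encode(xyz %*% t(.xyz2rgb)) * max_value
  out <- array(rgb, dim = if (is.null(dim(lab))) c(1L, 1L, 3L) else dim(lab))
  if (is.null(dim(lab))) c(out) else out
}

#' Quantize an sRGB image to 8-bit levels
#'
#' @param rgb Array of doubles in `[0, 1]`.
#' @return Integer array in `[0, 255]` of the same shape.
#' @export
quantize_rgb <- function(rgb) {
  q <- round(pmin(pmax(rgb, 0), 1) * 255)
  storage.mode(q) <- "integer"
  q
}
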