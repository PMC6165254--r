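#' sRGB to CIELab conversion
#'
#' Converts an 8-bit sRGB elastogram to the CIELab colour space
#' (sRGB gamma expansion, then linear RGB to XYZ under the D65 reference
#' white and the 2 degree standard observer, then the CIE L*a*b* transform).
#' CIELab separates lightness (L*, 0-100) from the two chromatic opponent
#' axes: a* opposes green (negative) to red (positive) and b* opposes blue
#' (negative) to yellow (positive). Red-hard tissue detection operates on a*,
#' where red pixels take large positive values.
#'
#' The reference white is taken as the exact XYZ image of RGB(255,255,255)
#' under the standard sRGB matrix, so neutral grays map to a* = b* = 0
#' exactly rather than to a small chromatic residual.
#'
#' @param image An [rgb_image].
#' @return A `lab_image`: a list with matrices `L`, `a`, `b` of the same
#'   spatial dimensions as `image`.
#' @examples
#' img <- rgb_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' lab <- rgb_to_cielab(img)
#' lab$a  # ~ +80: red is strongly positive on a*
#' @export
rgb_to_cielab <- function(image) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  d <- dim(image)
  m <- matrix(unclass(image), ncol = 3L)  # pixels x channels
  lab <- srgb_to_lab(m)
  structure(
    list(L = matrix(lab[, 1], d[1], d[2]),
         a = matrix(lab[, 2], d[1], d[2]),
         b = matrix(lab[, 3], d[1], d[2])),
    class = "lab_image"
  )
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image> %d x %d px; L* in [%.1f, %.1f], a* in [%.1f, %.1f]\n",
              nrow(x$L), ncol(x$L), min(x$L), max(x$L), min(x$a), max(x$a)))
  invisible(x)
}

#' Extract the a* (green-red) channel
#'
#' @param lab A `lab_image` from [rgb_to_cielab()].
#' @return A numeric matrix of a* values; red-dominant pixels are large and
#'   positive, green-dominant pixels negative.
#' @export
a_channel <- function(lab) {
  stopifnot(inherits(lab, "lab_image"))
  lab$a
}

# sRGB (IEC 61966-2-1) -> XYZ matrix, D65 / 2 degrees.
.srgb_xyz <- matrix(
  c(0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041),
  nrow = 3, byrow = TRUE
)
# White point = image of RGB(1,1,1): grays are exactly achromatic.
.lab_white <- rowSums(.srgb_xyz)

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

# rgb: n x 3 matrix in [0, 255] -> n x 3 Lab matrix
srgb_to_lab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_xyz)
  r <- sweep(xyz, 2L, .lab_white, "/")
  fx <- .lab_f(r[, 1]); fy <- .lab_f(r[, 2]); fz <- .lab_f(r[, 3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Inverse transform, used for round-trip validation. lab: n x 3 -> n x 3
# sRGB in [0, 255] (unclipped; out-of-gamut Lab yields values outside range).
lab_to_srgb <- function(lab) {
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.lab_finv(fx), .lab_finv(fy), .lab_finv(fz))
  xyz <- sweep(xyz, 2L, .lab_white, "*")
  lin <- xyz %*% t(solve(.srgb_xyz))
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  v * 255
}
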