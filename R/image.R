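#' RGB elastogram images
#'
#' An `rgb_image` is a height x width x 3 numeric array of 8-bit sRGB channel
#' values in \[0, 255\]. It is the raw input to the pipeline: a colour strain
#' elastogram in which blue encodes soft tissue (high strain) and red encodes
#' hard tissue (little or no strain).
#'
#' @param pixels A numeric array of dimension `c(height, width, 3)` with
#'   values in \[0, 255\], or in \[0, 1\] (as returned by [png::readPNG()]),
#'   in which case values are rescaled to \[0, 255\].
#' @return An object of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 array.",
          class = "elastocad_invalid_input")
  }
  if (any(dim(pixels)[1:2] < 1L) || length(pixels) == 0L) {
    abort("Image raster is empty.", class = "elastocad_invalid_input")
  }
  if (anyNA(pixels)) {
    abort("Image contains missing values.", class = "elastocad_invalid_input")
  }
  if (max(pixels) <= 1 && min(pixels) >= 0) pixels <- pixels * 255
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("Channel values must lie in [0, 255].",
          class = "elastocad_invalid_input")
  }
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, 3 channels (8-bit sRGB)\n", d[1], d[2]))
  invisible(x)
}

#' Read an elastogram image from PNG or TIFF
#'
#' Reads an 8-bit-per-channel RGB raster; an alpha channel, if present, is
#' dropped. Grayscale inputs are refused because colour is the signal here.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An [rgb_image].
#' @export
read_elastogram <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("No such image file: ", path), class = "elastocad_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("Unsupported image format: .", ext),
          class = "elastocad_io_error")
  )
  if (length(dim(raw)) != 3L || dim(raw)[3] < 3L) {
    abort("Expected an RGB image; got a grayscale raster.",
          class = "elastocad_io_error")
  }
  rgb_image(raw[, , 1:3, drop = FALSE] * 255)
}

#' Write an elastogram image to PNG
#'
#' @param image An [rgb_image].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_elastogram <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Overlay the hard mask on an elastogram
#'
#' Reproduces the system's reviewable output: one image in which the region
#' classified as hard is painted solid red and the rest keeps its original
#' colours, and (with `invert = TRUE`) its complement highlighting the soft
#' region.
#'
#' @param image An [rgb_image].
#' @param mask A logical matrix with the image's spatial dimensions.
#' @param colour Length-3 RGB vector (0-255) painted on masked pixels.
#' @param invert Paint the complement of `mask` instead.
#' @return An [rgb_image].
#' @export
mask_overlay <- function(image, mask, colour = c(255, 0, 0), invert = FALSE) {
  stopifnot(inherits(image, "rgb_image"), is.logical(mask))
  if (!identical(dim(image)[1:2], dim(mask))) {
    abort("Mask and image dimensions differ.", class = "elastocad_shape_error")
  }
  m <- if (invert) !mask else mask
  out <- unclass(image)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- colour[ch]
    out[, , ch] <- plane
  }
  rgb_image(out)
}
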