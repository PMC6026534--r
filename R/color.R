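#' sRGB to CIE L*a*b* conversion
#'
#' Standard sRGB to CIE L*a*b* under the D65 white point. Pure black maps
#' to L = 0, pure white to L = 100 with a, b approximately 0.
#'
#' @param image Integer H x W x 3 RGB array in \code{[0, 255]}.
#' @return Numeric H x W x 3 array of (L, a, b) values.
#' @export
rgb_to_lab <- function(image) {
  convert_space(image, "Lab")
}

#' sRGB to CIE L*u*v* conversion
#'
#' @param image Integer H x W x 3 RGB array in \code{[0, 255]}.
#' @return Numeric H x W x 3 array of (L, u, v) values.
#' @export
rgb_to_luv <- function(image) {
  convert_space(image, "Luv")
}

convert_space <- function(image, to) {
  image <- rgb_image(image)
  d <- dim(image)
  m <- matrix(as.numeric(image), ncol = 3L) / 255
  out <- grDevices::convertColor(m, from = "sRGB", to = to)
  array(out, dim = d)
}

#' Lab/Luv back to sRGB (for visualisation)
#'
#' @param image Numeric H x W x 3 array in the named space.
#' @param from Either \code{"Lab"} or \code{"Luv"}.
#' @return Integer H x W x 3 RGB array in \code{[0, 255]}.
#' @export
lab_to_rgb <- function(image, from = c("Lab", "Luv")) {
  from <- match.arg(from)
  d <- dim(image)
  m <- matrix(as.numeric(image), ncol = 3L)
  out <- grDevices::convertColor(m, from = from, to = "sRGB")
  rgb_image(array(as.integer(round(pmin(pmax(out, 0), 1) * 255)), dim = d))
}

# ITU-R 601 luma on an RGB array, integer gray levels 0..255
rgb_to_gray <- function(image) {
  image <- rgb_image(image)
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  matrix(as.integer(round(g)), dim(image)[1L], dim(image)[2L])
}
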