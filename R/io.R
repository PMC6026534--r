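#' Read an RGB image
#'
#' Reads a PNG, TIFF or JPEG file into an integer H x W x 3 array with
#' channel values in \code{[0, 255]}. Grayscale input is replicated across
#' the three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to an image file.
#' @return Integer array of dimension \code{c(H, W, 3)}.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores x (width) in the first dimension; transpose to row, col
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(t(dat), 3L), dim = c(ncol(dat), nrow(dat), 3L))
  } else if (dim(dat)[3L] < 3L) {
    dat <- array(rep(t(dat[, , 1L]), 3L), dim = c(dim(dat)[2L], dim(dat)[1L], 3L))
  } else {
    dat <- array(apply(dat[, , 1:3, drop = FALSE], 3L, t),
                 dim = c(dim(dat)[2L], dim(dat)[1L], 3L))
  }
  rgb_image(array(as.integer(round(pmin(pmax(dat, 0), 1) * 255)), dim = dim(dat)))
}

#' Construct / validate an RGB image array
#'
#' @param pixels Integer-valued H x W x 3 array in \code{[0, 255]}.
#' @return The validated array (invisibly classed as plain array).
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3L] != 3L) stop("RGB image must be H x W x 3")
  if (d[1L] < 1L || d[2L] < 1L) stop("image must have H >= 1, W >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  pixels
}

#' Write an RGB image as PNG
#'
#' @param path Output path.
#' @param image Integer H x W x 3 array in \code{[0, 255]}.
#' @export
write_image <- function(path, image) {
  image <- rgb_image(image)
  png::writePNG(array(image / 255, dim = dim(image)), path)
  invisible(NULL)
}

# Minimal 16-bit grayscale PNG encoder. The PNG codecs in this stack write
# 8 bits per sample only, which cannot hold label ids above 255; label maps
# therefore go through this encoder (zlib via memCompress, CRC32 via digest)
# and come back through png::readPNG, which reads 16-bit natively.
write_png16 <- function(path, mat) {
  h <- nrow(mat); w <- ncol(mat)
  crc32 <- function(raw) {
    as.raw(rev(as.integer(
      strtoi(substring(digest::digest(raw, algo = "crc32", serialize = FALSE),
                       c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L)
    )))[4:1]
  }
  u32 <- function(x) {
    as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, crc32(body))
  }
  # IHDR: width, height, bit depth 16, color type 0 (grayscale)
  ihdr <- c(u32(w), u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  vals <- as.integer(t(mat))
  samp <- as.raw(as.vector(rbind(vals %/% 256L, vals %% 256L)))
  rows <- matrix(samp, nrow = 2L * w)  # one column per scanline
  scan <- unlist(lapply(seq_len(h), function(i) c(as.raw(0L), rows[, i])),
                 use.names = FALSE)
  idat <- memCompress(scan, type = "gzip")
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  out <- c(sig, chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(NULL)
}

#' Write a label map as 16-bit grayscale PNG
#'
#' Label maps are integer rasters with 0 reserved for background/unlabelled.
#' Serialization is lossless for labels in \code{[0, 65535]}.
#'
#' @param path Output path.
#' @param labels Integer matrix of non-negative labels.
#' @export
write_label_map <- function(path, labels) {
  labels <- label_map(labels)
  if (max(labels) > 65535L) stop("label overflow: labels beyond 16 bits")
  write_png16(path, labels)
  invisible(NULL)
}

#' Read a label map from 16-bit grayscale PNG
#'
#' @param path Path to a single-channel PNG written by
#'   \code{\link{write_label_map}}.
#' @return Integer label matrix.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("cannot read label map: ", path)
  dat <- png::readPNG(path)
  if (length(dim(dat)) != 2L)
    stop("label map must be a single-channel image, got ",
         dim(dat)[3L], " channels")
  label_map(matrix(as.integer(round(dat * 65535)), nrow(dat), ncol(dat)))
}

#' Construct / validate a label map
#'
#' @param labels Matrix of non-negative integers; 0 means background.
#' @return Integer matrix.
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) stop("label map must be a matrix")
  if (anyNA(labels) || min(labels) < 0) stop("labels must be non-negative")
  storage.mode(labels) <- "integer"
  labels
}

#' Number of distinct non-zero labels in a label map
#'
#' @param labels Label matrix.
#' @return Integer count.
#' @export
n_labels <- function(labels) {
  length(setdiff(unique(as.vector(labels)), 0L))
}
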