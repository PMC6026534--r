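# Filter-bank visual words. The bank holds 17 linear filters: three
# Gaussians (sigma = 1, 2, 4) applied to each of L, a, b (nine responses,
# ordered by sigma then channel); four Laplacians of Gaussian
# (sigma = 1, 2, 4, 8) on L; and first-order Gaussian derivatives on L,
# x before y, each at sigma = 2, 4 (x = column axis, y = row axis).

gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- seq(-r, r)
  d2 <- outer(x^2, x^2, `+`)
  k <- (d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k - mean(k)  # exact zero response on constants after truncation
}

deriv_kernel <- function(sigma, axis = c("x", "y")) {
  axis <- match.arg(axis)
  r <- ceiling(3 * sigma)
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  dg <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  dg <- dg - mean(dg)  # antisymmetric, already ~0; enforce exactly
  if (axis == "x") outer(g, dg) else outer(dg, g)  # rows = y, cols = x
}

#' The 17-filter bank
#'
#' @return List of 17 entries, each with \code{kernel}, \code{family},
#'   \code{sigma} and \code{channel} (1 = L, 2 = a, 3 = b).
#' @export
filter_bank <- function() {
  bank <- list()
  for (s in c(1, 2, 4)) {
    for (ch in 1:3) {
      bank[[length(bank) + 1L]] <- list(kernel = gaussian_kernel(s),
                                        family = "gaussian", sigma = s,
                                        channel = ch)
    }
  }
  for (s in c(1, 2, 4, 8)) {
    bank[[length(bank) + 1L]] <- list(kernel = log_kernel(s), family = "log",
                                      sigma = s, channel = 1L)
  }
  for (axis in c("x", "y")) {
    for (s in c(2, 4)) {
      bank[[length(bank) + 1L]] <- list(kernel = deriv_kernel(s, axis),
                                        family = paste0("d", axis),
                                        sigma = s, channel = 1L)
    }
  }
  bank
}

# Symmetric (edge-repeating) reflection of an index sequence onto 1..n,
# valid for arbitrary padding via folding with period 2n.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  j <- (idx - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

# 2-D convolution with symmetric-reflection boundary handling; pads by
# the kernel radius with folded indices, convolves with EBImage::filter2
# (true convolution: the kernel is flipped) and crops back.
convolve_reflect <- function(channel, kernel) {
  h <- nrow(channel); w <- ncol(channel)
  rr <- (nrow(kernel) - 1L) %/% 2L
  rc <- (ncol(kernel) - 1L) %/% 2L
  padded <- channel[reflect_index(seq(1L - rr, h + rr), h),
                    reflect_index(seq(1L - rc, w + rc), w), drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(rr + 1L):(rr + h), (rc + 1L):(rc + w), drop = FALSE]
}

#' Per-pixel filter responses
#'
#' Convolves the L, a, b channels with the 17-filter bank using symmetric
#' reflective boundary handling.
#'
#' @param lab Numeric H x W x 3 CIE L*a*b* array.
#' @return Numeric H x W x 17 response array, ordered as
#'   \code{\link{filter_bank}}.
#' @export
compute_responses <- function(lab) {
  d <- dim(lab)
  if (length(d) != 3L || d[3L] != 3L) stop("expected an H x W x 3 Lab array")
  if (d[1L] < 2L || d[2L] < 2L) stop("image too small for filtering")
  bank <- filter_bank()
  out <- array(0, dim = c(d[1L], d[2L], length(bank)))
  for (f in seq_along(bank)) {
    out[, , f] <- convolve_reflect(lab[, , bank[[f]]$channel],
                                   bank[[f]]$kernel)
  }
  out
}

#' Dense grid patch descriptors
#'
#' Tiles the response raster with a patch grid and takes each patch's mean
#' response vector as its descriptor. Partial border patches are averaged
#' over their valid pixels, so every pixel keeps a word.
#'
#' @param responses H x W x F response array from
#'   \code{\link{compute_responses}}.
#' @param patch_size Patch edge in pixels.
#' @param stride Grid stride in pixels (defaults to \code{patch_size}).
#' @return List: \code{descriptors} (M x F matrix, patches enumerated
#'   column-major over the grid), \code{grid} (rows, cols), \code{centers}
#'   (M x 2, 0-based patch centre pixels), \code{patch_size},
#'   \code{stride}, \code{pixel_patch} (H x W map pixel -> patch id).
#' @export
extract_patch_descriptors <- function(responses, patch_size = 4L,
                                      stride = patch_size) {
  stopifnot(patch_size >= 1, stride >= 1)
  d <- dim(responses)
  h <- d[1L]; w <- d[2L]; nf <- d[3L]
  r0 <- seq(1L, h, by = stride)
  c0 <- seq(1L, w, by = stride)
  ngr <- length(r0); ngc <- length(c0)
  m <- ngr * ngc
  desc <- matrix(0, m, nf)
  centers <- matrix(0, m, 2)
  for (ci in seq_len(ngc)) {
    cols <- c0[ci]:min(c0[ci] + patch_size - 1L, w)
    for (ri in seq_len(ngr)) {
      rows <- r0[ri]:min(r0[ri] + patch_size - 1L, h)
      id <- (ci - 1L) * ngr + ri
      block <- responses[rows, cols, , drop = FALSE]
      desc[id, ] <- colMeans(matrix(block, length(rows) * length(cols), nf))
      centers[id, ] <- c(mean(rows) - 1, mean(cols) - 1)
    }
  }
  # pixel -> nearest patch centre (equals the containing tile when
  # stride == patch_size)
  ridx <- pmin(pmax(round((seq_len(h) - 1 - (patch_size - 1) / 2) / stride) + 1, 1), ngr)
  cidx <- pmin(pmax(round((seq_len(w) - 1 - (patch_size - 1) / 2) / stride) + 1, 1), ngc)
  pixel_patch <- outer(ridx, (cidx - 1L) * ngr, `+`)
  storage.mode(pixel_patch) <- "integer"
  list(descriptors = desc, grid = c(rows = ngr, cols = ngc),
       centers = centers, patch_size = as.integer(patch_size),
       stride = as.integer(stride), pixel_patch = pixel_patch)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[i + 1L] <- sample.int(n, 1L)
    } else {
      centers[i + 1L] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((x - matrix(x[centers[i + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Learn a visual dictionary by K-means
#'
#' K-means (Lloyd) with k-means++ initialization from the stated seed;
#' deterministic given the seed.
#'
#' @param descriptors M x F descriptor matrix.
#' @param n_words Dictionary size N (>= 2).
#' @param seed RNG seed.
#' @param iter_max Maximum Lloyd iterations.
#' @return List with \code{centers} (N x F), \code{n_words}, \code{seed}.
#' @export
learn_dictionary <- function(descriptors, n_words = 64L, seed = 1L,
                             iter_max = 50L) {
  descriptors <- as.matrix(descriptors)
  stopifnot(n_words >= 2, nrow(descriptors) >= n_words)
  with_seed(seed, {
    distinct <- unique(descriptors)
    if (nrow(distinct) < n_words) {
      warning("fewer distinct descriptors than words; duplicating centres")
      centers <- distinct[rep(seq_len(nrow(distinct)),
                              length.out = n_words), , drop = FALSE]
    } else {
      init <- unique(kmeanspp_init(descriptors, n_words))
      while (nrow(init) < n_words) {
        extra <- distinct[sample.int(nrow(distinct), n_words - nrow(init)), ,
                          drop = FALSE]
        init <- unique(rbind(init, extra))
      }
      fit <- suppressWarnings(
        stats::kmeans(descriptors, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd"))
      centers <- fit$centers
    }
    rownames(centers) <- NULL
    list(centers = centers, n_words = as.integer(n_words), seed = seed)
  })
}

#' Quantize descriptors into visual words
#'
#' Nearest-centre assignment \eqn{w_j = argmin_i ||G_j - c_i||^2}; ties
#' break to the lowest centre index.
#'
#' @param descriptors M x F matrix.
#' @param dictionary Result of \code{\link{learn_dictionary}}.
#' @return Integer vector of word ids in \code{[1, N]}.
#' @export
quantize <- function(descriptors, dictionary) {
  x <- as.matrix(descriptors)
  cts <- dictionary$centers
  if (ncol(x) != ncol(cts)) stop("descriptor dimension mismatch")
  d2 <- outer(rowSums(x^2), rep(1, nrow(cts))) - 2 * x %*% t(cts) +
    outer(rep(1, nrow(x)), rowSums(cts^2))
  max.col(-d2, ties.method = "first")
}

#' Word map: descriptors, grid and word assignment for one image
#'
#' @param image RGB array.
#' @param dictionary Visual dictionary.
#' @param patch_size,stride Grid geometry.
#' @return The patch structure of \code{\link{extract_patch_descriptors}}
#'   plus \code{words}.
#' @export
word_map <- function(image, dictionary, patch_size = 4L,
                     stride = patch_size) {
  lab <- rgb_to_lab(image)
  patches <- extract_patch_descriptors(compute_responses(lab), patch_size,
                                       stride)
  patches$words <- quantize(patches$descriptors, dictionary)
  patches
}

#' Word frequency table
#'
#' Counts per word id, sorted descending (ties to the lower word id); the
#' first row is the first major word.
#'
#' @param words Integer word-id vector or a word-map list with
#'   \code{$words}.
#' @return Data frame with columns \code{word}, \code{count}.
#' @export
word_frequency <- function(words) {
  if (is.list(words)) words <- words$words
  if (length(words) == 0L) stop("empty word map")
  tab <- table(words)
  ids <- as.integer(names(tab))
  cnt <- as.integer(tab)
  o <- order(-cnt, ids)
  data.frame(word = ids[o], count = cnt[o])
}
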