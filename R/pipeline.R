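# Plant foreground extraction and single-leaf instance segmentation:
# MSBS-LDA scene segmentation -> green-topic foreground -> fruit removal
# by R-B thresholding -> illumination diagnosis (and homomorphic
# correction when uneven) -> strong-edge removal -> distance-map centroid
# seeding -> marker-controlled watershed.

#' Plant foreground extraction
#'
#' Segments the scene with MSBS-LDA and selects the foreground topic. The
#' default rule picks the topic with the largest mean excess-green index
#' (2G - R - B) over its pixels and errors when no topic is
#' green-dominant; alternatives are an explicit topic id or the most
#' negative mean a* channel.
#'
#' @param image RGB array.
#' @param K Topic count (>= 2).
#' @param config \code{\link{msbs_config}}.
#' @param fg_rule "excess_green", "topic" or "a_neg".
#' @param topic_id Foreground topic when \code{fg_rule = "topic"}.
#' @param seed RNG seed.
#' @return Binary integer mask matrix (1 = plant); attribute
#'   \code{topic} records the chosen topic.
#' @export
extract_plant <- function(image, K = 2L, config = msbs_config(),
                          fg_rule = c("excess_green", "topic", "a_neg"),
                          topic_id = NULL, seed = 1L) {
  stopifnot(K >= 2)
  fg_rule <- match.arg(fg_rule)
  labels <- msbs_segment(image, K, config = config, seed = seed)
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  topic <- switch(fg_rule,
    topic = {
      if (is.null(topic_id)) stop("fg_rule = 'topic' needs topic_id")
      topic_id
    },
    excess_green = {
      exg <- 2 * image[, , 2L] - image[, , 1L] - image[, , 3L]
      sc <- vapply(present, function(k) mean(exg[labels == k]), numeric(1))
      if (max(sc) <= 0)
        stop("no green-dominant topic; supply fg_rule = 'topic' with an ",
             "explicit topic_id")
      present[which.max(sc)]
    },
    a_neg = {
      a <- rgb_to_lab(image)[, , 2L]
      sc <- vapply(present, function(k) mean(a[labels == k]), numeric(1))
      present[which.min(sc)]
    })
  mask <- matrix(0L, nrow(labels), ncol(labels))
  mask[labels == topic] <- 1L
  attr(mask, "topic") <- topic
  attr(mask, "labels") <- labels
  mask
}

#' Fruit removal by R - B thresholding
#'
#' Computes the signed colour difference D = R - B on the foreground and
#' splits it with Otsu's threshold. A bimodality guard skips removal when
#' the split is weak, so fruitless plants are left intact: removal
#' requires the between-class/total variance ratio to reach
#' \code{bimodality} and the class-mean gap to exceed \code{min_gap_sd}
#' pooled within-class standard deviations (Otsu's ratio alone is ~0.6
#' even for unimodal data, so the gap condition carries the decision).
#'
#' @param image RGB array.
#' @param mask Binary foreground mask.
#' @param threshold Fixed threshold on D overriding Otsu (optional).
#' @param bimodality Minimum between-class/total variance ratio (default
#'   0.2).
#' @param min_gap_sd Minimum class-mean gap in pooled within-class
#'   standard deviations (default 6).
#' @return List: \code{leaf_mask}, \code{fruit_mask} (binary matrices
#'   partitioning the foreground), \code{threshold} (NA when skipped).
#' @export
remove_fruit <- function(image, mask, threshold = NULL, bimodality = 0.2,
                         min_gap_sd = 6) {
  if (!any(mask > 0)) stop("empty foreground mask")
  D <- image[, , 1L] - image[, , 3L]
  vals <- D[mask > 0]
  fruit <- matrix(0L, nrow(mask), ncol(mask))
  if (is.null(threshold)) {
    lv <- as.integer(round(vals)) + 256L  # shift to 1..511
    counts <- tabulate(lv, 511L)
    ot <- otsu_threshold(counts)
    thr <- ot$level - 256L
    lo <- vals[vals <= thr]
    hi <- vals[vals > thr]
    weak <- !is.finite(ot$ratio) || ot$ratio < bimodality ||
      length(lo) == 0L || length(hi) == 0L
    if (!weak) {
      pooled <- sqrt((stats::var(lo) * length(lo) +
                        stats::var(hi) * length(hi)) / length(vals))
      weak <- !is.finite(pooled) ||
        (mean(hi) - mean(lo)) < min_gap_sd * max(pooled, 1e-9)
    }
    if (weak) {
      return(list(leaf_mask = mask + 0L, fruit_mask = fruit,
                  threshold = NA_real_))
    }
  } else {
    thr <- threshold
  }
  fruit[mask > 0 & D > thr] <- 1L
  leaf <- mask + 0L
  leaf[fruit == 1L] <- 0L
  list(leaf_mask = leaf, fruit_mask = fruit, threshold = thr)
}

# Morphological closing-then-opening with a disc brush; regularizes the
# staircase boundary of masks derived from patch-level topic labels.
smooth_mask <- function(mask, r) {
  br <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  m <- EBImage::Image(t(mask > 0))
  m <- EBImage::opening(EBImage::closing(m, br), br)
  out <- (t(EBImage::imageData(m)) > 0) + 0L
  out
}

# Otsu on an integer histogram; returns the maximizing level (threshold:
# class 2 is strictly above) and the between/total variance ratio.
otsu_threshold <- function(counts) {
  n <- sum(counts)
  lev <- seq_along(counts)
  mu <- sum(lev * counts) / n
  total_var <- sum(counts * (lev - mu)^2) / n
  w1 <- cumsum(counts)
  m1 <- cumsum(lev * counts)
  w2 <- n - w1
  between <- ifelse(w1 > 0 & w2 > 0,
                    (m1 / pmax(w1, 1) - (sum(lev * counts) - m1) /
                       pmax(w2, 1))^2 * w1 * w2 / n^2, 0)
  best <- which.max(between)
  list(level = best, ratio = if (total_var > 0) between[best] / total_var
                             else NA_real_)
}

#' Illumination diagnosis from the foreground gray histogram
#'
#' Grayscale distribution rate
#' \eqn{\alpha' = C_{hist}(M_s - R_s, M_s + R_s) / C_{hist}(1, 255)} with
#' gray radius \eqn{R_s = 255 \beta' / 2}; \eqn{M_s} is the window centre
#' maximizing the accumulated histogram mass. Gray level 0 encodes
#' masked-out pixels and is excluded. Illumination is even when
#' \eqn{\alpha'} exceeds \code{alpha_threshold}.
#'
#' @param gray Integer gray matrix 0..255 (0 = outside the mask).
#' @param beta_prime Grayscale distribution range (default 0.2).
#' @param alpha_threshold Decision threshold (default 0.8).
#' @return List: \code{alpha_prime}, \code{M_s}, \code{R_s},
#'   \code{decision} ("even" or "uneven").
#' @export
illumination_check <- function(gray, beta_prime = 0.2,
                               alpha_threshold = 0.8) {
  stopifnot(beta_prime > 0, beta_prime < 1)
  counts <- tabulate(as.integer(gray[gray > 0]), 255L)
  total <- sum(counts)
  if (total == 0L) stop("no foreground pixels (all gray values are 0)")
  r_s <- 255 * beta_prime / 2
  mass <- vapply(1:255, function(m) {
    lo <- max(1L, as.integer(ceiling(m - r_s)))
    hi <- min(255L, as.integer(floor(m + r_s)))
    sum(counts[lo:hi])
  }, numeric(1))
  m_s <- which.max(mass)
  alpha_prime <- mass[m_s] / total
  list(alpha_prime = alpha_prime, M_s = m_s, R_s = r_s,
       decision = if (alpha_prime > alpha_threshold) "even" else "uneven")
}

#' Homomorphic illumination correction
#'
#' Log transform, Gaussian high-emphasis filtering in the frequency
#' domain with low/high gains (\code{gamma_l}, \code{gamma_h}) and cutoff
#' \code{d0}, exponentiation, and a multiplicative rescale that restores
#' the input's mean brightness before clipping to [0, 255] (an additive
#' min-max rescale would destroy the intensity ratios the filter just
#' equalized). Attenuates slow illumination variation while keeping
#' reflectance detail.
#'
#' @param gray Numeric gray matrix (>= 0).
#' @param gamma_l,gamma_h Low/high frequency gains (defaults 0.5, 2).
#' @param d0 Gaussian cutoff in cycles (default 30).
#' @return Integer gray matrix in [0, 255].
#' @export
homomorphic_correct <- function(gray, gamma_l = 0.5, gamma_h = 2, d0 = 30) {
  h <- nrow(gray); w <- ncol(gray)
  f <- log(gray + 1)
  fr <- stats::fft(f)
  ku <- pmin(seq_len(h) - 1L, h - (seq_len(h) - 1L))
  kv <- pmin(seq_len(w) - 1L, w - (seq_len(w) - 1L))
  d2 <- outer(ku^2, kv^2, `+`)
  H <- gamma_l + (gamma_h - gamma_l) * (1 - exp(-d2 / (2 * d0^2)))
  g <- Re(stats::fft(fr * H, inverse = TRUE)) / (h * w)
  out <- exp(g) - 1
  out[out < 0] <- 0
  if (mean(out) > 1e-12) out <- out * mean(gray) / mean(out)
  matrix(as.integer(round(pmin(pmax(out, 0), 255))), h, w)
}

#' Strong leaf-leaf edge detection
#'
#' Default detector: Sobel gradient magnitude with canny-style
#' non-maximum suppression and hysteresis thresholding (quantile-based,
#' computed inside the mask); alternatively an externally computed edge
#' probability map (e.g. from a structured-edge detector) binarized at a
#' threshold. Edges are restricted to the leaf mask.
#'
#' @param gray Numeric gray matrix.
#' @param mask Binary leaf mask.
#' @param detector "gradient" or "external".
#' @param external Edge probability matrix (for "external").
#' @param high_q Quantile of the in-mask gradient magnitude used as the
#'   strong threshold (default 0.85).
#' @param low_frac Weak threshold as a fraction of the strong one
#'   (default 0.5).
#' @param ext_threshold Binarization threshold for "external" (default
#'   0.5).
#' @return Binary edge matrix (subset of the mask).
#' @export
detect_strong_edges <- function(gray, mask,
                                detector = c("gradient", "external"),
                                external = NULL, high_q = 0.85,
                                low_frac = 0.5, ext_threshold = 0.5) {
  detector <- match.arg(detector)
  h <- nrow(gray); w <- ncol(gray)
  if (detector == "external") {
    if (is.null(external) || !all(dim(external) == c(h, w)))
      stop("external edge map missing or size mismatch")
    edges <- matrix(0L, h, w)
    edges[external >= ext_threshold & mask > 0] <- 1L
    return(edges)
  }
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # cols = x
  sy <- t(sx)
  gx <- convolve_reflect(gray, sx)
  gy <- convolve_reflect(gray, sy)
  mag <- sqrt(gx^2 + gy^2)
  if (!any(mask > 0)) return(matrix(0L, h, w))
  strong_thr <- stats::quantile(mag[mask > 0], high_q, names = FALSE)
  if (strong_thr < 1e-6) return(matrix(0L, h, w))  # flat image
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  at <- function(m, dr, dc) {
    rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
    m[rs, cs]
  }
  nms <- matrix(TRUE, h, w)
  for (sct in 0:3) {
    o <- offs[[sct + 1L]]
    sel <- sector == sct
    keep <- mag >= at(mag, o[1], o[2]) & mag >= at(mag, -o[1], -o[2])
    nms[sel & !keep] <- FALSE
  }
  weak <- mag >= strong_thr * low_frac & nms
  strong <- mag >= strong_thr & nms
  # hysteresis: keep weak components that contain a strong pixel
  comp <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(weak)))))
  keep_ids <- unique(comp[strong & comp > 0])
  edges <- matrix(0L, h, w)
  edges[comp > 0 & comp %in% keep_ids & mask > 0] <- 1L
  edges
}

#' Leaf centroid location on the edge-subtracted distance map
#'
#' Computes the Euclidean distance transform of (mask minus edges), finds
#' the grayscale-dilation local maxima with a disk of
#' \code{dilation_radius} that reach at least \code{min_distance}, and
#' merges maxima closer than \code{dilation_radius} to their centroid.
#'
#' @param mask Binary leaf mask.
#' @param edges Binary edge raster.
#' @param min_distance Minimum distance-map value of a seed (pixels).
#' @param dilation_radius Disk radius for the local-maximum filter.
#' @return Numeric matrix of centroids (0-based row, col), possibly with
#'   zero rows (with a warning).
#' @export
locate_centroids <- function(mask, edges = NULL, min_distance = 5,
                             dilation_radius = 5) {
  if (!any(mask > 0)) stop("empty mask")
  interior <- mask > 0
  if (!is.null(edges)) interior <- interior & !(edges > 0)
  D <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(interior)))))
  brush <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L,
                              shape = "disc")
  Dd <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(D)), brush)))
  is_max <- D >= Dd & D >= min_distance
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no distance-map maxima found")
    return(matrix(numeric(0), 0, 2))
  }
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1)
  # single-linkage merge of maxima closer than dilation_radius
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  d2 <- as.matrix(stats::dist(pts))^2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && d2[i, j] < dilation_radius^2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- t(vapply(unique(roots), function(r) {
    colMeans(pts[roots == r, , drop = FALSE])
  }, numeric(2)))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Marker-controlled watershed leaf segmentation
#'
#' Floods the negated distance map of the leaf mask from the centroid
#' markers (labels 1..L), restricted to the mask, using seeded region
#' propagation; the split-line raster marks boundaries between adjacent
#' instances.
#'
#' @param mask Binary leaf mask.
#' @param centroids Matrix of (0-based row, col) seeds.
#' @return List: \code{instances} (label matrix 1..L inside the mask),
#'   \code{centroids}, \code{split_lines} (binary matrix).
#' @export
watershed_leaves <- function(mask, centroids) {
  stopifnot(nrow(centroids) >= 1)
  h <- nrow(mask); w <- ncol(mask)
  D <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask > 0)))))
  seeds <- matrix(0L, h, w)
  rr <- pmin(pmax(round(centroids[, 1]) + 1L, 1L), h)
  cc <- pmin(pmax(round(centroids[, 2]) + 1L, 1L), w)
  seeds[cbind(rr, cc)] <- seq_len(nrow(centroids))
  inst <- EBImage::propagate(EBImage::Image(t(-D)), EBImage::Image(t(seeds)),
                             mask = EBImage::Image(t(mask > 0)))
  inst <- t(EBImage::imageData(inst))
  storage.mode(inst) <- "integer"
  split_lines <- matrix(0L, h, w)
  at <- function(m, dr, dc) {
    rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
    m[rs, cs]
  }
  for (d in list(c(1, 0), c(0, 1))) {
    nb <- at(inst, d[1], d[2])
    split_lines[inst > 0L & nb > 0L & nb != inst] <- 1L
  }
  list(instances = label_map(inst), centroids = centroids,
       split_lines = split_lines)
}

#' Full single-leaf segmentation chain
#'
#' Plant extraction (MSBS-LDA), fruit removal, illumination diagnosis
#' with homomorphic correction applied only when the lighting is uneven,
#' strong-edge detection, centroid location and marker-controlled
#' watershed.
#'
#' @param image RGB array.
#' @param K Topics for plant extraction (default 2).
#' @param config \code{\link{msbs_config}} for the extraction stage.
#' @param seed RNG seed.
#' @param fg_rule,topic_id Foreground topic rule (see
#'   \code{\link{extract_plant}}).
#' @param min_distance,dilation_radius Centroid parameters.
#' @param beta_prime,alpha_threshold Illumination parameters.
#' @param gamma_l,gamma_h,d0 Homomorphic filter parameters.
#' @param high_q,low_frac Edge detector thresholds.
#' @param smooth_radius Disc radius of the morphological closing/opening
#'   that regularizes the patch-resolution foreground mask before the
#'   distance transform (0 disables).
#' @return List: \code{instances}, \code{centroids}, \code{fg_mask},
#'   \code{leaf_mask}, \code{fruit_mask}, \code{edges},
#'   \code{illumination} (report incl. \code{corrected} flag),
#'   \code{split_lines}.
#' @export
segment_leaves <- function(image, K = 2L, config = msbs_config(), seed = 1L,
                           fg_rule = "excess_green", topic_id = NULL,
                           min_distance = 5, dilation_radius = 9,
                           beta_prime = 0.2, alpha_threshold = 0.8,
                           gamma_l = 0.5, gamma_h = 2, d0 = 30,
                           high_q = 0.85, low_frac = 0.5,
                           smooth_radius = 3L) {
  fg <- extract_plant(image, K, config, fg_rule, topic_id, seed)
  fr <- remove_fruit(image, fg)
  if (smooth_radius > 0) {
    fr$leaf_mask <- smooth_mask(fr$leaf_mask, as.integer(smooth_radius))
    fr$leaf_mask[fr$fruit_mask == 1L] <- 0L
  }
  gray <- rgb_to_gray(image)
  gray[fr$leaf_mask == 0L] <- 0L
  rep_ <- illumination_check(gray, beta_prime, alpha_threshold)
  rep_$corrected <- rep_$decision == "uneven"
  g_use <- gray
  if (rep_$corrected) {
    g_use <- homomorphic_correct(gray, gamma_l, gamma_h, d0)
    g_use[fr$leaf_mask == 0L] <- 0L
  }
  edges <- detect_strong_edges(g_use, fr$leaf_mask, high_q = high_q,
                               low_frac = low_frac)
  cents <- locate_centroids(fr$leaf_mask, edges, min_distance,
                            dilation_radius)
  if (nrow(cents) == 0L) {
    return(list(instances = label_map(matrix(0L, nrow(gray), ncol(gray))),
                centroids = cents, fg_mask = fg,
                leaf_mask = fr$leaf_mask, fruit_mask = fr$fruit_mask,
                edges = edges, illumination = rep_,
                split_lines = matrix(0L, nrow(gray), ncol(gray))))
  }
  ws <- watershed_leaves(fr$leaf_mask, cents)
  list(instances = ws$instances, centroids = cents, fg_mask = fg,
       leaf_mask = fr$leaf_mask, fruit_mask = fr$fruit_mask, edges = edges,
       illumination = rep_, split_lines = ws$split_lines)
}
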