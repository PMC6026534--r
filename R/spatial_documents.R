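# Word -> document assignment strategies. A document assignment is a
# data.frame with one row per token instance: word (id), doc (document
# id), source (originating grid token; duplicated rows share a source for
# overlapping rectangles).

#' Rectangular documents
#'
#' Tiles the patch grid with r1 x r2 rectangles (patch units). In the
#' non-overlapping scheme the stride equals the rectangle; in the
#' overlapping scheme the stride is half the rectangle in each axis
#' (rounded up), so each interior token is covered by up to four
#' documents. Border documents are clipped.
#'
#' @param wm Word map from \code{\link{word_map}}.
#' @param r1,r2 Rectangle size in patch rows/cols.
#' @param overlapping Use the half-shift scheme.
#' @return List: \code{assign} (data.frame word/doc/source),
#'   \code{n_docs}, \code{multiplicity} (per source token).
#' @export
rect_documents <- function(wm, r1, r2, overlapping = FALSE) {
  stopifnot(r1 >= 1, r2 >= 1)
  ngr <- wm$grid[["rows"]]; ngc <- wm$grid[["cols"]]
  if (r1 > ngr && r2 > ngc) {
    warning("rectangle larger than the patch grid; single document")
  }
  ri <- ((seq_len(ngr * ngc) - 1L) %% ngr) + 1L
  ci <- ((seq_len(ngr * ngc) - 1L) %/% ngr) + 1L
  if (!overlapping) {
    dr <- (ri - 1L) %/% r1
    dc <- (ci - 1L) %/% r2
    doc <- dc * (((ngr - 1L) %/% r1) + 1L) + dr + 1L
    assign <- data.frame(word = wm$words, doc = as.integer(doc),
                         source = seq_along(wm$words))
  } else {
    sr <- max(1L, as.integer(ceiling(r1 / 2)))
    sc <- max(1L, as.integer(ceiling(r2 / 2)))
    or_rows <- seq(1L, ngr, by = sr)
    or_cols <- seq(1L, ngc, by = sc)
    doc_of <- function(o_r, o_c) {
      which(or_rows == o_r) + (which(or_cols == o_c) - 1L) * length(or_rows)
    }
    rows_cover <- lapply(seq_len(ngr), function(r) {
      or_rows[or_rows <= r & r <= or_rows + r1 - 1L]
    })
    cols_cover <- lapply(seq_len(ngc), function(cc) {
      or_cols[or_cols <= cc & cc <= or_cols + r2 - 1L]
    })
    lst <- vector("list", length(ri))
    for (t in seq_along(ri)) {
      ors <- rows_cover[[ri[t]]]
      ocs <- cols_cover[[ci[t]]]
      docs <- as.integer(outer(match(ors, or_rows),
                               (match(ocs, or_cols) - 1L) * length(or_rows),
                               `+`))
      lst[[t]] <- data.frame(word = wm$words[t], doc = docs, source = t)
    }
    assign <- do.call(rbind, lst)
  }
  n_docs <- max(assign$doc)
  mult <- tabulate(assign$source, length(wm$words))
  list(assign = assign, n_docs = n_docs, multiplicity = mult,
       overlapping = overlapping, r1 = r1, r2 = r2)
}

#' SLIC super-pixels
#'
#' Grid-seeded local k-means in labxy space (the SLIC algorithm): seeds on
#' a regular grid of step \eqn{S = \sqrt{HW/n}}, distance
#' \eqn{D^2 = d_{lab}^2 + (m/S)^2 d_{xy}^2} with compactness m, search
#' windows of 2S, followed by a connectivity-enforcement step that
#' reassigns stray components to an adjacent super-pixel.
#'
#' @param image RGB array.
#' @param n_segments Target number of super-pixels (>= 2).
#' @param compactness Compactness m (default 10).
#' @param n_iter Local k-means iterations (default 10).
#' @return Integer H x W super-pixel label matrix (labels 1..n).
#' @export
slic_superpixels <- function(image, n_segments, compactness = 10,
                             n_iter = 10L) {
  stopifnot(n_segments >= 2)
  lab <- rgb_to_lab(image)
  h <- dim(lab)[1L]; w <- dim(lab)[2L]
  s <- sqrt(h * w / n_segments)
  cr <- seq(s / 2, h - s / 2 + 1e-9, by = s)
  cc <- seq(s / 2, w - s / 2 + 1e-9, by = s)
  if (length(cr) == 0L) cr <- h / 2
  if (length(cc) == 0L) cc <- w / 2
  centers <- cbind(rep(cr, times = length(cc)),
                   rep(cc, each = length(cr)))
  k <- nrow(centers)
  cl <- matrix(0, k, 5)  # r, c, L, a, b
  for (i in seq_len(k)) {
    r0 <- pmin(pmax(round(centers[i, 1] + 0.5), 1), h)
    c0 <- pmin(pmax(round(centers[i, 2] + 0.5), 1), w)
    cl[i, ] <- c(centers[i, 1], centers[i, 2], lab[r0, c0, 1],
                 lab[r0, c0, 2], lab[r0, c0, 3])
  }
  m2 <- (compactness / s)^2
  gr <- outer(seq_len(h) - 1, rep(1, w))
  gc <- outer(rep(1, h), seq_len(w) - 1)
  labels <- matrix(1L, h, w)
  for (it in seq_len(n_iter)) {
    dist <- matrix(Inf, h, w)
    for (i in seq_len(k)) {
      r0 <- max(1L, floor(cl[i, 1] - s)); r1 <- min(h, ceiling(cl[i, 1] + s) + 1L)
      c0 <- max(1L, floor(cl[i, 2] - s)); c1 <- min(w, ceiling(cl[i, 2] + s) + 1L)
      rs <- r0:r1; cs <- c0:c1
      dlab <- (lab[rs, cs, 1] - cl[i, 3])^2 + (lab[rs, cs, 2] - cl[i, 4])^2 +
        (lab[rs, cs, 3] - cl[i, 5])^2
      dxy <- (gr[rs, cs] - cl[i, 1])^2 + (gc[rs, cs] - cl[i, 2])^2
      d2 <- dlab + m2 * dxy
      upd <- d2 < dist[rs, cs]
      sub <- labels[rs, cs]; sub[upd] <- i
      labels[rs, cs] <- sub
      sub <- dist[rs, cs]; sub[upd] <- d2[upd]
      dist[rs, cs] <- sub
    }
    for (i in seq_len(k)) {
      msk <- labels == i
      if (!any(msk)) next
      cl[i, ] <- c(mean(gr[msk]), mean(gc[msk]), mean(lab[, , 1][msk]),
                   mean(lab[, , 2][msk]), mean(lab[, , 3][msk]))
    }
  }
  enforce_connectivity(labels)
}

# Keep each label's largest 4-connected component; iteratively flood
# orphan pixels with a 4-neighbour's surviving label.
enforce_connectivity <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  orphan <- matrix(FALSE, h, w)
  for (i in sort(unique(as.vector(labels)))) {
    comp <- EBImage::bwlabel(EBImage::Image(t(labels == i)))
    comp <- t(EBImage::imageData(comp))
    if (max(comp) > 1) {
      sizes <- tabulate(comp[comp > 0])
      keep <- which.max(sizes)
      orphan[comp > 0 & comp != keep] <- TRUE
    }
  }
  shift <- function(m, dr, dc, fill) {
    out <- matrix(fill, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    vr <- rs >= 1 & rs <= h; vc <- cs >= 1 & cs <= w
    out[vr, vc] <- m[rs[vr], cs[vc]]
    out
  }
  while (any(orphan)) {
    progressed <- FALSE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb_lab <- shift(labels, d[1], d[2], 0L)
      nb_orph <- shift(orphan, d[1], d[2], TRUE)
      fix <- orphan & !nb_orph & nb_lab > 0L
      if (any(fix)) {
        labels[fix] <- nb_lab[fix]
        orphan[fix] <- FALSE
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  storage.mode(labels) <- "integer"
  labels
}

#' SLIC documents
#'
#' Assigns each grid token to the super-pixel containing its centre pixel;
#' every token gets exactly one document.
#'
#' @param image RGB array.
#' @param wm Word map.
#' @param n_segments,compactness SLIC parameters.
#' @param seed Accepted for interface uniformity (SLIC is deterministic).
#' @return Same structure as \code{\link{rect_documents}} plus
#'   \code{superpixels}.
#' @export
slic_documents <- function(image, wm, n_segments = 64L, compactness = 10,
                           seed = 1L) {
  sp <- slic_superpixels(image, n_segments, compactness)
  ctr_r <- pmin(pmax(floor(wm$centers[, 1L]) + 1L, 1L), nrow(sp))
  ctr_c <- pmin(pmax(floor(wm$centers[, 2L]) + 1L, 1L), ncol(sp))
  doc <- sp[cbind(ctr_r, ctr_c)]
  doc <- match(doc, sort(unique(doc)))  # compact ids
  assign <- data.frame(word = wm$words, doc = as.integer(doc),
                       source = seq_along(wm$words))
  list(assign = assign, n_docs = max(doc),
       multiplicity = rep(1L, length(wm$words)), overlapping = FALSE,
       superpixels = sp)
}

#' Spatial-LDA segmentation with a chosen document strategy
#'
#' Composes visual words, a document assignment (whole image, rectangles,
#' SLIC super-pixels, or mean-shift via \code{\link{msbs_segment}}), the
#' collapsed-Gibbs LDA fit (with geometric-mean fusion for overlapping
#' documents), and the max-posterior label map.
#'
#' @param image RGB array.
#' @param K Topic count.
#' @param strategy One of "whole", "nr", "or", "slic", "msbs".
#' @param dictionary Optional dictionary; learned from the image if NULL.
#' @param params List of strategy parameters (r1, r2, n_segments,
#'   compactness, patch_size, stride, n_words, n_iter, burn_in, thin,
#'   alpha, beta; msbs takes a full \code{\link{msbs_config}}).
#' @param seed RNG seed.
#' @return Integer label matrix 1..K.
#' @export
segment_spatial_lda <- function(image, K,
                                strategy = c("whole", "nr", "or", "slic",
                                             "msbs"),
                                dictionary = NULL, params = list(),
                                seed = 1L) {
  strategy <- match.arg(strategy)
  p <- utils::modifyList(list(r1 = 8L, r2 = 8L, n_segments = 64L,
                              compactness = 10, patch_size = 4L,
                              stride = NULL, n_words = 64L, n_iter = 500L,
                              burn_in = 200L, thin = 10L, alpha = NULL,
                              beta = 0.01, n_chains = 5L), params)
  if (is.null(p$stride)) p$stride <- p$patch_size
  if (strategy == "msbs") {
    cfg_args <- p[names(p) %in% names(formals(msbs_config))]
    cfg <- do.call(msbs_config, cfg_args)
    return(msbs_segment(image, K, dictionary, cfg, seed))
  }
  seeds <- with_seed(seed, child_seeds(3L))
  if (is.null(dictionary)) {
    lab <- rgb_to_lab(image)
    patches <- extract_patch_descriptors(compute_responses(lab),
                                         p$patch_size, p$stride)
    dictionary <- learn_dictionary(patches$descriptors, p$n_words,
                                   seed = seeds[1L])
    patches$words <- quantize(patches$descriptors, dictionary)
    wm <- patches
  } else {
    wm <- word_map(image, dictionary, p$patch_size, p$stride)
  }
  da <- switch(strategy,
    whole = list(assign = data.frame(word = wm$words, doc = 1L,
                                     source = seq_along(wm$words)),
                 n_docs = 1L, overlapping = FALSE),
    nr = rect_documents(wm, p$r1, p$r2, overlapping = FALSE),
    or = rect_documents(wm, p$r1, p$r2, overlapping = TRUE),
    slic = slic_documents(image, wm, p$n_segments, p$compactness,
                          seed = seeds[2L]))
  priors <- dirichlet_priors(K, dictionary$n_words,
                             alpha = if (is.null(p$alpha)) 50 / K else p$alpha,
                             beta = p$beta)
  fit <- gibbs_fit(da$assign, K, priors, p$n_iter, p$burn_in, p$thin,
                   seed = seeds[3L], n_words = dictionary$n_words,
                   n_chains = p$n_chains)
  post <- if (isTRUE(da$overlapping)) {
    fuse_overlapping(fit$posterior, fit$corpus$source)
  } else {
    fit$posterior[order(fit$corpus$source), , drop = FALSE]
  }
  label_by_max_topic(post, wm$pixel_patch)
}
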