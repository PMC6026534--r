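# Synthetic scenes and corpora. Every generator seeds the RNG once per
# top-level call and derives child seeds deterministically, so scenes are
# bit-reproducible from (seed, parameters); the caller's RNG state is
# restored afterwards.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

child_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

clip255 <- function(x) {
  array(as.integer(round(pmin(pmax(x, 0), 255))), dim = dim(x))
}

inside_ellipse <- function(h, w, r0, c0, a, b, theta) {
  dr <- outer(seq_len(h) - 1 - r0, rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - 1 - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  u * u + v * v <= 1
}

inside_disk <- function(h, w, r0, c0, rad) {
  dr <- outer(seq_len(h) - 1 - r0, rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - 1 - c0)
  dr * dr + dc * dc <= rad * rad
}

paint <- function(image, mask, rgb) {
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- rgb[ch]
    image[, , ch] <- plane
  }
  image
}

default_blob_palette <- function(k) {
  pal <- matrix(c(
    200,  60,  60,
     60, 170,  70,
     70,  90, 200,
    220, 200,  60,
    160,  70, 190,
     70, 200, 200,
    230, 140,  60,
    120, 120, 120), ncol = 3, byrow = TRUE)
  if (k > nrow(pal)) stop("default palette supports at most ", nrow(pal), " regions")
  pal[seq_len(k), , drop = FALSE]
}

#' Synthetic blob scene
#'
#' Paints \code{k_regions} compact regions (Voronoi cells of random seed
#' points) with distinct colours, adds i.i.d. Gaussian pixel noise, and
#' optionally recolours a fraction of pixels inside region 1 as dark
#' speckles emulating disease lesions. The ground truth records the
#' noiseless partition; speckles keep their parent region's label.
#'
#' @param h,w Image size in pixels.
#' @param k_regions Number of regions (>= 1).
#' @param colors Optional k x 3 matrix of RGB colours; defaults to a
#'   well-separated palette.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param lesion_frac Fraction in \code{[0, 0.5)} of region-1 pixels
#'   recoloured as dark speckles.
#' @param seed RNG seed.
#' @return List with \code{image} (RGB array), \code{gt_regions} (label
#'   matrix), \code{seed} and \code{params}.
#' @export
make_blob_scene <- function(h, w, k_regions, colors = NULL, noise_sd = 0,
                            lesion_frac = 0, seed = 1L) {
  stopifnot(k_regions >= 1, lesion_frac >= 0, lesion_frac < 0.5)
  if (is.null(colors)) colors <- default_blob_palette(k_regions)
  colors <- as.matrix(colors)
  if (nrow(colors) < k_regions) stop("fewer colors than regions")
  if (anyDuplicated(colors[seq_len(k_regions), , drop = FALSE]))
    stop("colors must be distinct")
  with_seed(seed, {
    sr <- runif(k_regions, 0, h - 1)
    sc <- runif(k_regions, 0, w - 1)
    gr <- outer(seq_len(h) - 1, rep(1, w))
    gc <- outer(rep(1, h), seq_len(w) - 1)
    d2 <- vapply(seq_len(k_regions),
                 function(k) as.vector((gr - sr[k])^2 + (gc - sc[k])^2),
                 numeric(h * w))
    gt <- matrix(max.col(-d2, ties.method = "first"), h, w)
    img <- array(0, dim = c(h, w, 3))
    for (k in seq_len(k_regions)) img <- paint(img, gt == k, colors[k, ])
    lesion_mask <- matrix(FALSE, h, w)
    if (lesion_frac > 0) {
      in1 <- gt == 1L
      lesion_mask[in1] <- runif(sum(in1)) < lesion_frac
      img <- paint(img, lesion_mask, round(colors[1, ] * 0.2))
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
    list(image = clip255(img), gt_regions = label_map(gt),
         lesion_mask = lesion_mask, seed = seed,
         params = list(h = h, w = w, k_regions = k_regions,
                       noise_sd = noise_sd, lesion_frac = lesion_frac))
  })
}

#' Synthetic plant scene
#'
#' Overlapping green leaf ellipses in a rosette arrangement (distinct
#' shades, darker one-pixel rims where leaves meet) over a textured soil
#' background, with optional red fruit disks, moss speckle texture on the
#' background, and a multiplicative linear illumination ramp.
#'
#' Ground truth: \code{gt_regions} holds semantic classes (1 soil, 2 leaf,
#' 3 fruit, 4 moss), \code{gt_leaves} assigns every visible leaf pixel to
#' its topmost leaf (instances 1..n_leaves), \code{fruit_mask} is binary.
#'
#' @param h,w Image size.
#' @param n_leaves Number of leaves (>= 1).
#' @param fruit_count Number of red fruit disks.
#' @param moss Add moss speckle clumps on the background.
#' @param illum_gradient Apply a left-to-right multiplicative ramp from
#'   \code{1 - illum_strength} to \code{1 + illum_strength}.
#' @param illum_strength Ramp half-amplitude (default 0.25).
#' @param noise_sd Pixel noise on the composed scene (default 3).
#' @param seed RNG seed.
#' @return List with \code{image}, \code{gt_regions}, \code{gt_leaves},
#'   \code{fruit_mask}, \code{seed}, \code{params}.
#' @export
make_plant_scene <- function(h, w, n_leaves, fruit_count = 0, moss = FALSE,
                             illum_gradient = FALSE, illum_strength = 0.25,
                             noise_sd = 3, seed = 1L) {
  stopifnot(n_leaves >= 1)
  with_seed(seed, {
    base <- min(h, w)
    img <- array(0, dim = c(h, w, 3))
    soil <- c(115, 85, 55)
    for (ch in 1:3) img[, , ch] <- soil[ch] + rnorm(h * w, sd = 6)
    gt_leaves <- matrix(0L, h, w)
    cr <- (h - 1) / 2 + runif(1, -2, 2)
    cc <- (w - 1) / 2 + runif(1, -2, 2)
    angles <- 2 * pi * (seq_len(n_leaves) - 1) / n_leaves +
      runif(n_leaves, -0.10, 0.10)
    # petal-like rosette: leaves radiate outward and overlap neighbours
    # only moderately (pairwise overlap stays well under a third of a
    # leaf), which mirrors a mildly occluded top-view plant
    offs <- runif(n_leaves, 0.22, 0.26) * base
    alen <- runif(n_leaves, 0.15, 0.19) * base
    blen <- alen * runif(n_leaves, 0.42, 0.55)
    shade <- round(seq(110, 185, length.out = n_leaves))[sample.int(n_leaves)]
    leaf_rgb <- cbind(round(shade * 0.35), shade, round(shade * 0.35))
    for (i in seq_len(n_leaves)) {
      m <- inside_ellipse(h, w, cr + offs[i] * cos(angles[i]),
                          cc + offs[i] * sin(angles[i]),
                          alen[i], blen[i], angles[i])
      gt_leaves[m] <- i
      img <- paint(img, m, leaf_rgb[i, ])
    }
    # darker 1-px rims where a leaf touches a different leaf
    pad <- function(m, dr, dc) {
      out <- matrix(0L, h, w)
      rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
      cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
      out[] <- m[rs, cs]
      out
    }
    rim <- matrix(FALSE, h, w)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- pad(gt_leaves, d[1], d[2])
      rim <- rim | (gt_leaves > 0L & nb > 0L & nb != gt_leaves)
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[rim] <- plane[rim] * 0.45
      img[, , ch] <- plane
    }
    fruit_mask <- matrix(0L, h, w)
    if (fruit_count > 0) {
      frad <- 0.06 * base
      placed <- 0
      centers <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (placed < fruit_count && tries < 500) {
        tries <- tries + 1
        ang <- runif(1, 0, 2 * pi)
        rr <- cr + runif(1, 0.12, 0.22) * base * cos(ang)
        cz <- cc + runif(1, 0.12, 0.22) * base * sin(ang)
        if (rr < frad + 1 || rr > h - frad - 2 ||
            cz < frad + 1 || cz > w - frad - 2) next
        if (placed > 0 &&
            min(sqrt((centers[, 1] - rr)^2 + (centers[, 2] - cz)^2)) <
              2.6 * frad) next
        m <- inside_disk(h, w, rr, cz, frad)
        fruit_mask[m] <- 1L
        img <- paint(img, m, c(205, 45, 40))
        gt_leaves[m] <- 0L
        centers <- rbind(centers, c(rr, cz))
        placed <- placed + 1
      }
      if (placed < fruit_count) stop("could not place all fruits")
    }
    moss_mask <- matrix(FALSE, h, w)
    if (moss) {
      bg <- gt_leaves == 0L & fruit_mask == 0L
      n_clumps <- max(3L, round(h * w / 2000))
      for (i in seq_len(n_clumps)) {
        m <- inside_disk(h, w, runif(1, 0, h - 1), runif(1, 0, w - 1),
                         runif(1, 0.03, 0.06) * base)
        moss_mask <- moss_mask | (m & bg)
      }
      speck <- matrix(runif(h * w) < 0.7, h, w)
      moss_mask <- moss_mask & speck
      img <- paint(img, moss_mask, c(95, 115, 45))
    }
    # enforce visibility of every leaf instance
    for (i in seq_len(n_leaves)) {
      if (!any(gt_leaves == i)) stop("leaf ", i, " fully occluded; change seed")
    }
    gt_regions <- matrix(1L, h, w)
    gt_regions[gt_leaves > 0L] <- 2L
    gt_regions[fruit_mask == 1L] <- 3L
    gt_regions[moss_mask] <- 4L
    if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
    if (illum_gradient) {
      ramp <- seq(1 - illum_strength, 1 + illum_strength, length.out = w)
      for (ch in 1:3) img[, , ch] <- sweep(img[, , ch], 2, ramp, `*`)
    }
    list(image = clip255(img), gt_regions = label_map(gt_regions),
         gt_leaves = label_map(gt_leaves),
         fruit_mask = label_map(fruit_mask), seed = seed,
         params = list(h = h, w = w, n_leaves = n_leaves,
                       fruit_count = fruit_count, moss = moss,
                       illum_gradient = illum_gradient,
                       illum_strength = illum_strength, noise_sd = noise_sd))
  })
}

#' Forward-simulate an LDA corpus with known parameters
#'
#' Exact simulation of the LDA generative model: per-document topic
#' proportions \eqn{\theta_i \sim Dir(\alpha)}, per-topic word
#' distributions \eqn{\phi_k \sim Dir(\beta)}, then for every token a topic
#' \eqn{z \sim Discrete(\theta_i)} and a word \eqn{w \sim Discrete(\phi_z)}.
#'
#' @param n_docs,vocab_size,k_topics,tokens_per_doc Corpus dimensions.
#' @param alpha Scalar or K-vector Dirichlet concentration for topics.
#' @param beta Scalar, V-vector, or K x V matrix of Dirichlet
#'   concentrations for words; a matrix row parameterises one topic, which
#'   allows block-separated topics.
#' @param seed RNG seed.
#' @return List with \code{docs} (list of word-id vectors),
#'   \code{theta_true} (docs x K), \code{phi_true} (K x V), \code{z_true}.
#' @export
make_lda_corpus <- function(n_docs, vocab_size, k_topics, alpha = 1,
                            beta = 1, tokens_per_doc = 100, seed = 1L) {
  stopifnot(n_docs >= 1, vocab_size >= 1, k_topics >= 1, tokens_per_doc >= 1,
            all(alpha > 0), all(beta > 0))
  if (length(alpha) == 1L) alpha <- rep(alpha, k_topics)
  if (is.matrix(beta)) {
    stopifnot(nrow(beta) == k_topics, ncol(beta) == vocab_size)
  } else {
    if (length(beta) == 1L) beta <- rep(beta, vocab_size)
    beta <- matrix(beta, k_topics, vocab_size, byrow = TRUE)
  }
  rdirichlet <- function(a) {
    g <- rgamma(length(a), shape = a)
    g / sum(g)
  }
  with_seed(seed, {
    theta <- matrix(vapply(seq_len(n_docs), function(i) rdirichlet(alpha),
                           numeric(k_topics)),
                    nrow = k_topics)
    theta <- t(theta)
    phi <- matrix(vapply(seq_len(k_topics),
                         function(k) rdirichlet(beta[k, ]),
                         numeric(vocab_size)),
                  nrow = vocab_size)
    phi <- t(phi)
    docs <- vector("list", n_docs)
    z_true <- vector("list", n_docs)
    for (i in seq_len(n_docs)) {
      z <- sample.int(k_topics, tokens_per_doc, replace = TRUE,
                      prob = theta[i, ])
      wds <- vapply(z, function(k) {
        sample.int(vocab_size, 1L, prob = phi[k, ])
      }, integer(1))
      docs[[i]] <- wds
      z_true[[i]] <- z
    }
    list(docs = docs, theta_true = theta, phi_true = phi, z_true = z_true,
         seed = seed)
  })
}
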