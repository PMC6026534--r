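# MSBS-LDA driver: the spatial bandwidth h_s comes from word-frequency
# statistics, the range bandwidth h_r from an iterative search that runs
# mean-shift document assignment + LDA at each candidate and tracks the
# mean pairwise LUV separation of the resulting classes.

#' MSBS configuration
#'
#' @param C Constant of the h_s formula, in [1.41, 1.67]; default 1.5
#'   (interval midpoint).
#' @param hr_init Initial range bandwidth (LUV units).
#' @param hr_min Smallest range bandwidth tried.
#' @param tol Stability tolerance on consecutive class separations
#'   (default 1).
#' @param jump_factor Relative-increase factor defining a "large jump" for
#'   the fallback rule.
#' @param thr,s_thr,max_iter Mean-shift convergence controls.
#' @param min_size Minimum mean-shift cluster size (pixels).
#' @param n_words,patch_size,stride Visual-word parameters.
#' @param n_iter,burn_in,thin LDA sweep schedule.
#' @param n_chains LDA restarts per iteration (best chain kept by
#'   collapsed joint likelihood).
#' @param alpha,beta Dirichlet concentrations (NULL: 50/K and 0.01).
#' @return Config list.
#' @export
msbs_config <- function(C = 1.5, hr_init = 40, hr_min = 2, tol = 1,
                        jump_factor = 1, thr = 0.1, s_thr = 0.5,
                        max_iter = 100L, min_size = 20L, n_words = 64L,
                        patch_size = 4L, stride = patch_size,
                        n_iter = 500L, burn_in = 200L, thin = 10L,
                        n_chains = 3L, alpha = NULL, beta = 0.01) {
  stopifnot(C >= 1.41, C <= 1.67, hr_init > hr_min, hr_min > 0, tol > 0)
  list(C = C, hr_init = hr_init, hr_min = hr_min, tol = tol,
       jump_factor = jump_factor, thr = thr, s_thr = s_thr,
       max_iter = as.integer(max_iter), min_size = as.integer(min_size),
       n_words = as.integer(n_words), patch_size = as.integer(patch_size),
       stride = as.integer(stride), n_iter = as.integer(n_iter),
       burn_in = as.integer(burn_in), thin = as.integer(thin),
       n_chains = as.integer(n_chains), alpha = alpha, beta = beta)
}

#' Spatial bandwidth from word frequencies
#'
#' \eqn{h_s = 10^C \cdot w^{(1)}_{fren} / N}, with \eqn{w^{(1)}_{fren}}
#' the count of the most frequent visual word and N the total token count,
#' so the ratio is the top word's proportion. Clamped to >= 1 pixel.
#'
#' @param freq Frequency table from \code{\link{word_frequency}}.
#' @param C Constant in [1.41, 1.67].
#' @return Bandwidth in pixels.
#' @export
spatial_bandwidth <- function(freq, C = 1.5) {
  stopifnot(C >= 1.41, C <= 1.67, nrow(freq) >= 1)
  max(1, 10^C * freq$count[1L] / sum(freq$count))
}

#' Mean pairwise LUV separation of segmentation classes
#'
#' Per-class mean (L, U, V) colours, then the mean Euclidean distance over
#' all unordered class pairs,
#' \eqn{\Delta\bar E = 2 \sum_{i<j} ||\bar c_i - \bar c_j|| / (K(K-1))}.
#' Classes absent from the map are excluded, reducing K.
#'
#' @param labels Label matrix with labels drawn from 1..K.
#' @param luv H x W x 3 LUV array (typically the mean-shift filtered
#'   image).
#' @return Scalar separation.
#' @export
mean_luv_separation <- function(labels, luv) {
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  k <- length(present)
  if (k < 2L) stop("need at least 2 present classes for the separation")
  means <- t(vapply(present, function(lbl) {
    m <- labels == lbl
    c(mean(luv[, , 1L][m]), mean(luv[, , 2L][m]), mean(luv[, , 3L][m]))
  }, numeric(3)))
  d <- as.matrix(stats::dist(means))
  sum(d[upper.tri(d)]) * 2 / (k * (k - 1))
}

#' Stability rule on the separation trace
#'
#' TRUE when the three most recent values are all present (non-NA) and
#' pairwise differ by less than \code{tol}.
#'
#' @param deltas Separation values recorded so far.
#' @param tol Tolerance (default 1).
#' @return Logical.
#' @export
msbs_stable <- function(deltas, tol = 1) {
  n <- length(deltas)
  if (n < 3L) return(FALSE)
  last3 <- deltas[(n - 2L):n]
  if (anyNA(last3)) return(FALSE)
  (max(last3) - min(last3)) < tol
}

#' Fallback jump rule on a completed trace
#'
#' The first step whose increase exceeds \code{jump_factor} times the
#' previous value (the first large jump); if no step qualifies, the step
#' with the maximal single increase. Returns the index of the iteration
#' the jump lands on.
#'
#' @param deltas Complete separation trace (NAs allowed, skipped).
#' @param jump_factor Relative threshold (default 1, i.e. more than
#'   doubling).
#' @return Index into \code{deltas}.
#' @export
msbs_jump_index <- function(deltas, jump_factor = 1) {
  ok <- which(!is.na(deltas))
  if (length(ok) == 0L) stop("no valid separations in trace")
  if (length(ok) == 1L) return(ok)
  v <- deltas[ok]
  inc <- diff(v)
  big <- which(inc > jump_factor * abs(v[-length(v)]))
  if (length(big) > 0L) return(ok[big[1L] + 1L])
  ok[which.max(inc) + 1L]
}

# Candidate h_r sequence: step 1 down to 10, step 0.5 below 10.
hr_sequence <- function(hr_init, hr_min) {
  out <- numeric(0)
  h <- hr_init
  while (h >= hr_min) {
    out <- c(out, h)
    h <- h - if (h < 10) 0.5 else 1
  }
  out
}

#' Iterative range-bandwidth search
#'
#' For each candidate h_r (descending from \code{hr_init}, step 1, step
#' 0.5 once below 10): mean-shift filter the LUV image at (h_s, h_r),
#' cluster the modes into documents, fit LDA with K topics over the visual
#' words, and record the class separation of the resulting label map on
#' the filtered image. Stops at the first iteration where the last three
#' separations pairwise differ by less than \code{tol} and returns that
#' iteration's map; if the trace never stabilizes, returns the map at the
#' first large jump.
#'
#' @param image RGB array.
#' @param K Topic count.
#' @param dictionary Optional visual dictionary; learned from the image
#'   when NULL.
#' @param config \code{\link{msbs_config}} result.
#' @param seed RNG seed (drives dictionary learning and every LDA fit).
#' @return List: \code{labels} (chosen map), \code{trace} (data.frame
#'   h_r, n_docs, delta_e), \code{chosen} (trace row), \code{stop_reason}
#'   (three-stable / first-jump / exhausted), \code{h_s}.
#' @export
search_hr <- function(image, K, dictionary = NULL, config = msbs_config(),
                      seed = 1L) {
  hrs <- hr_sequence(config$hr_init, config$hr_min)
  seeds <- with_seed(seed, child_seeds(length(hrs) + 1L))
  if (is.null(dictionary)) {
    lab <- rgb_to_lab(image)
    patches <- extract_patch_descriptors(compute_responses(lab),
                                         config$patch_size, config$stride)
    dictionary <- learn_dictionary(patches$descriptors, config$n_words,
                                   seed = seeds[length(seeds)])
    patches$words <- quantize(patches$descriptors, dictionary)
    wm <- patches
  } else {
    wm <- word_map(image, dictionary, config$patch_size, config$stride)
  }
  h_s <- spatial_bandwidth(word_frequency(wm), config$C)
  luv <- rgb_to_luv(image)
  priors <- dirichlet_priors(
    K, dictionary$n_words,
    alpha = if (is.null(config$alpha)) 50 / K else config$alpha,
    beta = config$beta)
  # patch centre pixels, 1-based
  ctr_r <- pmin(pmax(floor(wm$centers[, 1L]) + 1L, 1L), dim(luv)[1L])
  ctr_c <- pmin(pmax(floor(wm$centers[, 2L]) + 1L, 1L), dim(luv)[2L])
  deltas <- rep(NA_real_, length(hrs))
  ndocs <- integer(length(hrs))
  maps <- vector("list", length(hrs))
  stop_reason <- "exhausted"
  chosen <- NA_integer_
  for (i in seq_along(hrs)) {
    ms <- filter_image(luv, h_s, hrs[i], config$thr, config$s_thr,
                       config$max_iter)
    cl <- cluster_modes(ms, h_s, hrs[i], config$min_size)
    ndocs[i] <- cl$n_clusters
    doc <- cl$cluster[cbind(ctr_r, ctr_c)]
    corpus <- data.frame(word = wm$words, doc = doc,
                         source = seq_along(wm$words))
    fit <- gibbs_fit(corpus, K, priors, config$n_iter, config$burn_in,
                     config$thin, seed = seeds[i],
                     n_words = dictionary$n_words,
                     n_chains = config$n_chains)
    labels <- label_by_max_topic(fit$posterior, wm$pixel_patch)
    maps[[i]] <- labels
    deltas[i] <- tryCatch(mean_luv_separation(labels, ms$filtered),
                          error = function(e) NA_real_)
    if (msbs_stable(deltas[seq_len(i)], config$tol)) {
      chosen <- i
      stop_reason <- "three-stable"
      break
    }
  }
  if (is.na(chosen)) {
    if (all(is.na(deltas)))
      stop("no iteration produced >= 2 classes")
    chosen <- msbs_jump_index(deltas, config$jump_factor)
    stop_reason <- "first-jump"
  }
  done <- which(!vapply(maps, is.null, logical(1)))
  trace <- data.frame(h_r = hrs[done], n_docs = ndocs[done],
                      delta_e = deltas[done])
  list(labels = maps[[chosen]], trace = trace, chosen = chosen,
       stop_reason = stop_reason, h_s = h_s)
}

#' MSBS-LDA segmentation
#'
#' Full pipeline: visual words and dictionary, h_s from the top word
#' frequency, iterative h_r search with mean-shift documents and LDA, and
#' the chosen K-class label map.
#'
#' @inheritParams search_hr
#' @return Label matrix with labels 1..K; attributes \code{trace},
#'   \code{stop_reason}, \code{h_s}.
#' @export
msbs_segment <- function(image, K, dictionary = NULL,
                         config = msbs_config(), seed = 1L) {
  res <- search_hr(image, K, dictionary, config, seed)
  out <- res$labels
  attr(out, "trace") <- res$trace
  attr(out, "stop_reason") <- res$stop_reason
  attr(out, "h_s") <- res$h_s
  out
}
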