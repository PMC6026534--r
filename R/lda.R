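#' Symmetric Dirichlet priors
#'
#' Conventional LDA defaults: \eqn{\alpha_k = 50/K}, \eqn{\beta_w = 0.01}.
#'
#' @param K Topic count.
#' @param n_words Vocabulary size.
#' @param alpha,beta Scalars or full vectors.
#' @return List with K-vector \code{alpha} and N-vector \code{beta}.
#' @export
dirichlet_priors <- function(K, n_words, alpha = 50 / K, beta = 0.01) {
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(beta) == 1L) beta <- rep(beta, n_words)
  stopifnot(length(alpha) == K, length(beta) == n_words,
            all(alpha > 0), all(beta > 0))
  list(alpha = alpha, beta = beta)
}

# Build the flat token representation the sampler consumes. `docs` may be
# a list of word-id vectors (one per document) or a data.frame with
# columns word, doc and optionally source (the originating token, used to
# fuse duplicated tokens of overlapping documents).
as_corpus <- function(docs, n_words = NULL) {
  if (is.data.frame(docs)) {
    words <- as.integer(docs$word)
    doc_id <- as.integer(docs$doc)
    source <- if (!is.null(docs$source)) as.integer(docs$source)
              else seq_along(words)
  } else {
    words <- unlist(docs, use.names = FALSE)
    doc_id <- rep.int(seq_along(docs), lengths(docs))
    source <- seq_along(words)
  }
  if (length(words) == 0L) stop("empty corpus")
  if (is.null(n_words)) n_words <- max(words)
  stopifnot(all(words >= 1L), all(words <= n_words))
  list(words = words, docs = doc_id, source = source,
       n_words = as.integer(n_words), n_docs = max(doc_id))
}

#' Collapsed-Gibbs LDA fit
#'
#' Sweeps all tokens, resampling each topic label from the collapsed
#' conditional with the token's own counts removed. Per-token posteriors
#' \eqn{\phi_i^d = P(z | w_i, d)} are the empirical distribution of the
#' sampled labels over the retained (post burn-in, thinned) sweeps;
#' \eqn{\theta} and \eqn{\Phi} are averages of the standard smoothed count
#' ratios over the same sweeps.
#'
#' @param docs List of word-id vectors or a data.frame (see details).
#' @param K Topic count (>= 1).
#' @param priors \code{\link{dirichlet_priors}} result; defaults applied
#'   when NULL.
#' @param n_iter,burn_in,thin Sweep schedule.
#' @param seed RNG seed.
#' @param n_words Vocabulary size (defaults to the max word id).
#' @param n_chains Independent restarts; the chain with the highest
#'   collapsed joint log-likelihood p(w, z) at its final state is kept
#'   (the collapsed posterior is multimodal and single chains can lock a
#'   poor mode).
#' @return List with \code{z}, \code{posterior} (tokens x K),
#'   \code{theta}, \code{phi}, count matrices \code{nkw}, \code{ndk},
#'   \code{log_joint}, the corpus and schedule metadata.
#' @export
gibbs_fit <- function(docs, K, priors = NULL, n_iter = 500L, burn_in = 200L,
                      thin = 10L, seed = 1L, n_words = NULL, n_chains = 1L) {
  stopifnot(K >= 1, n_iter > burn_in, burn_in >= 0, thin >= 1, n_chains >= 1)
  corpus <- as_corpus(docs, n_words)
  if (is.null(priors)) priors <- dirichlet_priors(K, corpus$n_words)
  if (K > 200L) warning("K = ", K, " is unusually large")
  seeds <- with_seed(seed, child_seeds(n_chains))
  fit <- NULL
  for (ch in seq_len(n_chains)) {
    f <- with_seed(seeds[ch], {
      gibbs_lda_cpp(corpus$words, corpus$docs, corpus$n_words,
                    corpus$n_docs, as.integer(K), priors$alpha,
                    priors$beta, as.integer(n_iter), as.integer(burn_in),
                    as.integer(thin))
    })
    if (is.null(fit) || f$log_joint > fit$log_joint) fit <- f
  }
  fit$corpus <- corpus
  fit$K <- as.integer(K)
  fit$priors <- priors
  fit$schedule <- c(n_iter = n_iter, burn_in = burn_in, thin = thin)
  fit$seed <- seed
  fit
}

#' Collapsed conditional for one token
#'
#' Normalized \eqn{p(z_j = k | z_{-j}, w, d)} computed from the count
#' matrices with token j's counts removed (the \eqn{-j} convention). This
#' is the reference expression the sampler draws from; exported for
#' verification.
#'
#' @param fit A \code{\link{gibbs_fit}} result (state: z and counts).
#' @param token_j Token index.
#' @return Normalized K-vector.
#' @export
conditional_probability <- function(fit, token_j) {
  corpus <- fit$corpus
  w <- corpus$words[token_j]
  d <- corpus$docs[token_j]
  gibbs_conditional_cpp(fit$nkw, fit$ndk, w, d, fit$z[token_j],
                        fit$priors$alpha, fit$priors$beta)
}

# Plain-R evaluation of the same conditional, used as an independent
# oracle in tests.
conditional_probability_ref <- function(z, words, docs, K, n_words, alpha,
                                        beta, token_j) {
  keep <- seq_along(z) != token_j
  p <- numeric(K)
  for (k in seq_len(K)) {
    nkw <- sum(z[keep] == k & words[keep] == words[token_j])
    nk <- sum(z[keep] == k)
    ndk <- sum(z[keep] == k & docs[keep] == docs[token_j])
    nd <- sum(docs[keep] == docs[token_j])
    p[k] <- (nkw + beta[words[token_j]]) / (nk + sum(beta)) *
      (ndk + alpha[k]) / (nd + sum(alpha))
  }
  p / sum(p)
}

#' Fuse posteriors of tokens duplicated across overlapping documents
#'
#' For a source token covered by several documents the fused posterior is
#' the geometric mean of the per-document posteriors,
#' \eqn{\phi_i = exp(mean_d log \phi_i^d)}, renormalized. Tokens covered
#' once pass through unchanged.
#'
#' @param posterior Tokens x K posterior matrix (token instances).
#' @param source Integer vector mapping each instance to its source token.
#' @return Source-tokens x K fused, renormalized posterior matrix.
#' @export
fuse_overlapping <- function(posterior, source) {
  stopifnot(nrow(posterior) == length(source))
  K <- ncol(posterior)
  n_src <- max(source)
  lp <- log(posterior)
  out <- matrix(0, n_src, K)
  cnt <- tabulate(source, n_src)
  for (k in seq_len(K)) {
    out[, k] <- rowsum(lp[, k], source, reorder = TRUE)[, 1L] / cnt
  }
  out <- exp(out)
  rs <- rowSums(out)
  bad <- !is.finite(rs) | rs == 0
  if (any(bad)) {
    warning("zero posterior mass for ", sum(bad), " tokens; uniform fallback")
    out[bad, ] <- 1 / K
    rs[bad] <- 1
  }
  out / rs
}

#' Pixel label map from per-token posteriors
#'
#' Each token takes the topic with the largest posterior probability (ties
#' to the lowest topic index); pixels inherit their patch's label through
#' the pixel-to-patch provenance map.
#'
#' @param posterior Source-tokens x K matrix.
#' @param pixel_patch H x W map from pixel to patch/token id.
#' @return Integer label matrix with labels in \code{1..K}.
#' @export
label_by_max_topic <- function(posterior, pixel_patch) {
  lab_tok <- max.col(posterior, ties.method = "first")
  label_map(matrix(lab_tok[pixel_patch], nrow(pixel_patch),
                   ncol(pixel_patch)))
}
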