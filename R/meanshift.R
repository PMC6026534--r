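# Joint spatial-range mean-shift. Points live in the 5-d space
# [px, py, l, u, v]; h_s carries pixel units, h_r LUV units, and the two
# domains are screened separately (no coordinate normalization). With the
# Epanechnikov profile the shadow g() is the unit-ball indicator, so a
# shift step is the plain mean of the in-window samples.

#' Epanechnikov profile and kernel
#'
#' \code{epanechnikov_profile} is the profile k(x) = 1 - x on [0, 1], 0
#' elsewhere; its shadow \code{epanechnikov_shadow} is the indicator of
#' [0, 1]. \code{epanechnikov_kernel} evaluates
#' K_E = (d+2)/2 (1 - ||x||^2) on the unit ball (as conventionally
#' printed); with \code{normalized = TRUE} it is divided by the unit-ball
#' volume so that it integrates to one, the form used inside
#' \code{\link{kde}}.
#'
#' @param x Profile argument (squared norm), >= 0.
#' @param x_normsq Squared norm ||x||^2.
#' @param d Dimension.
#' @param normalized Divide by the volume of the d-ball.
#' @return Kernel/profile value(s).
#' @export
epanechnikov_profile <- function(x) {
  ifelse(x >= 0 & x <= 1, 1 - x, 0)
}

#' @rdname epanechnikov_profile
#' @export
epanechnikov_shadow <- function(x) {
  as.numeric(x >= 0 & x <= 1)
}

#' @rdname epanechnikov_profile
#' @export
epanechnikov_kernel <- function(x_normsq, d, normalized = FALSE) {
  v <- 0.5 * (d + 2) * epanechnikov_profile(x_normsq)
  if (normalized) v <- v / unit_ball_volume(d)
  v
}

unit_ball_volume <- function(d) pi^(d / 2) / gamma(d / 2 + 1)

#' Kernel density estimate
#'
#' \eqn{\hat f(x) = (1 / (N h^d)) \sum_n K((x_n - x)/h)} with the
#' normalized Epanechnikov kernel.
#'
#' @param point Numeric d-vector.
#' @param samples N x d matrix.
#' @param h Bandwidth (> 0).
#' @return Density value.
#' @export
kde <- function(point, samples, h) {
  samples <- as.matrix(samples)
  stopifnot(h > 0, nrow(samples) >= 1)
  d <- ncol(samples)
  u2 <- rowSums(sweep(samples, 2, point)^2) / h^2
  sum(epanechnikov_kernel(u2, d, normalized = TRUE)) / (nrow(samples) * h^d)
}

# KDE over the joint space with separate bandwidths: the kernel is the
# product of an Epanechnikov kernel on the spatial part (h_s) and one on
# the range part (h_r). Used for the ascent diagnostics along mode
# trajectories.
kde_joint <- function(point, samples, h_s, h_r) {
  samples <- as.matrix(samples)
  us <- rowSums(sweep(samples[, 1:2, drop = FALSE], 2, point[1:2])^2) / h_s^2
  ur <- rowSums(sweep(samples[, -(1:2), drop = FALSE], 2, point[-(1:2)])^2) / h_r^2
  dr <- ncol(samples) - 2L
  ks <- epanechnikov_kernel(us, 2L, normalized = TRUE)
  kr <- epanechnikov_kernel(ur, dr, normalized = TRUE)
  sum(ks * kr) / (nrow(samples) * h_s^2 * h_r^dr)
}

#' One mean-shift step
#'
#' Candidates are the samples within \code{h_s} of the current point in
#' the spatial domain; each is weighted by the shadow profile of its range
#' distance (for Epanechnikov, the indicator of the range ball), and the
#' new point is the weighted mean in both the spatial and the range
#' components.
#'
#' @param y Current 5-d point (px, py, l, u, v).
#' @param samples N x 5 matrix of joint points.
#' @param h_s,h_r Spatial and range bandwidths.
#' @return Updated 5-d point; attribute \code{empty} flags an empty
#'   window (point returned unchanged).
#' @export
mean_shift_step <- function(y, samples, h_s, h_r) {
  samples <- as.matrix(samples)
  ds2 <- rowSums(sweep(samples[, 1:2, drop = FALSE], 2, y[1:2])^2)
  keep <- ds2 <= h_s^2
  if (!any(keep)) {
    out <- y
    attr(out, "empty") <- TRUE
    return(out)
  }
  cand <- samples[keep, , drop = FALSE]
  g <- epanechnikov_shadow(
    rowSums(sweep(cand[, 3:5, drop = FALSE], 2, y[3:5])^2) / h_r^2)
  if (sum(g) == 0) {
    out <- y
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- colSums(cand * g) / sum(g)
  attr(out, "empty") <- FALSE
  out
}

#' Mode search from one starting point
#'
#' Iterates \code{\link{mean_shift_step}} from \code{y_0 = x_i} until the
#' spatial component is quasi-stationary (move <= \code{s_thr}) and the
#' range move is <= \code{thr}, or \code{max_iter} is reached.
#'
#' @param start 5-d starting point.
#' @param samples N x 5 sample matrix.
#' @param h_s,h_r Bandwidths.
#' @param thr Range convergence threshold (LUV units).
#' @param s_thr Spatial stationarity threshold (pixels).
#' @param max_iter Iteration cap.
#' @return List with \code{mode}, \code{n_iter}, \code{converged},
#'   \code{trajectory} (matrix of visited points).
#' @export
find_mode <- function(start, samples, h_s, h_r, thr = 0.1, s_thr = 0.5,
                      max_iter = 100L) {
  stopifnot(thr > 0)
  y <- as.numeric(start)
  traj <- matrix(y, 1)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    y2 <- mean_shift_step(y, samples, h_s, h_r)
    if (isTRUE(attr(y2, "empty"))) break
    ds <- sqrt(sum((y2[1:2] - y[1:2])^2))
    dr <- sqrt(sum((y2[3:5] - y[3:5])^2))
    y <- as.numeric(y2)
    traj <- rbind(traj, y)
    if (ds <= s_thr && dr <= thr) {
      converged <- TRUE
      break
    }
  }
  list(mode = y, n_iter = it, converged = converged, trajectory = traj)
}

#' Mean-shift filtering of a LUV image
#'
#' Runs the mode search from every pixel of the joint [px, py, l, u, v]
#' cloud and assigns each pixel its mode's colour.
#'
#' @param luv Numeric H x W x 3 LUV array.
#' @param h_s,h_r Bandwidths (> 0).
#' @param thr,s_thr,max_iter Convergence controls (see
#'   \code{\link{find_mode}}).
#' @return List: \code{filtered} (H x W x 3 LUV array), \code{modes}
#'   (n x 5 matrix, pixels column-major, coordinates 0-based),
#'   \code{iters}, \code{converged}.
#' @export
filter_image <- function(luv, h_s, h_r, thr = 0.1, s_thr = 0.5,
                         max_iter = 100L) {
  stopifnot(h_s > 0, h_r > 0, thr > 0)
  d <- dim(luv)
  res <- meanshift_filter_cpp(luv[, , 1L], luv[, , 2L], luv[, , 3L],
                              h_s, h_r, thr, s_thr, as.integer(max_iter))
  filtered <- array(c(res$modes[, 3L], res$modes[, 4L], res$modes[, 5L]),
                    dim = d)
  list(filtered = filtered, modes = res$modes, iters = res$iters,
       converged = res$converged)
}

#' Cluster converged modes into documents
#'
#' Modes are merged transitively when within \code{h_s / 2} spatially and
#' \code{h_r / 2} in range; clusters smaller than \code{min_size} are then
#' merged into the cluster with the nearest mean mode colour.
#'
#' @param mode_field Result of \code{\link{filter_image}} (or an n x 5
#'   mode matrix).
#' @param h_s,h_r The bandwidths used for filtering.
#' @param min_size Minimum surviving cluster size in pixels.
#' @param dim_hw Image dimensions c(H, W); required when a bare matrix is
#'   passed.
#' @return List: \code{cluster} (H x W integer matrix of document ids),
#'   \code{n_clusters}, \code{sizes}, \code{means} (cluster mean modes).
#' @export
cluster_modes <- function(mode_field, h_s, h_r, min_size = 20L,
                          dim_hw = NULL) {
  modes <- if (is.list(mode_field)) mode_field$modes else mode_field
  if (is.null(dim_hw)) {
    if (is.list(mode_field)) dim_hw <- dim(mode_field$filtered)[1:2]
    else stop("dim_hw required for a bare mode matrix")
  }
  cl <- cluster_modes_cpp(modes, h_s / 2, h_r / 2)
  n <- max(cl)
  sizes <- tabulate(cl, n)
  means <- matrix(0, n, 5)
  for (j in 1:5) means[, j] <- rowsum(modes[, j], cl)[, 1L] / sizes
  # merge undersized clusters into the nearest-in-range neighbour
  while (n > 1L && any(sizes < min_size)) {
    i <- which(sizes < min_size)[which.min(sizes[sizes < min_size])]
    others <- setdiff(seq_len(n), i)
    dr <- colSums((t(means[others, 3:5, drop = FALSE]) - means[i, 3:5])^2)
    tgt <- others[which.min(dr)]
    means[tgt, ] <- (means[tgt, ] * sizes[tgt] + means[i, ] * sizes[i]) /
      (sizes[tgt] + sizes[i])
    sizes[tgt] <- sizes[tgt] + sizes[i]
    cl[cl == i] <- tgt
    cl[cl > i] <- cl[cl > i] - 1L
    means <- means[-i, , drop = FALSE]
    sizes <- sizes[-i]
    n <- n - 1L
  }
  list(cluster = matrix(cl, dim_hw[1L], dim_hw[2L]),
       n_clusters = n, sizes = sizes, means = means)
}
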