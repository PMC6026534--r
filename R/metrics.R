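# Segmentation evaluation: class matching, SA/OR/UR, Dice, best Dice /
# symmetric best Dice, difference in count, modified Hausdorff distance,
# and report tables.

#' Match result classes to ground-truth classes
#'
#' One-to-one assignment maximizing the total pixel overlap, solved as a
#' maximum-weight bipartite matching (Hungarian) on the overlap matrix.
#' Unmatched classes map to NA.
#'
#' @param gt,ar Label matrices of the same shape (0 = background,
#'   excluded).
#' @return List: \code{gt_classes}, \code{ar_classes}, \code{match}
#'   (named integer vector gt class -> ar class, NA when unmatched),
#'   \code{overlap} (matrix of pixel overlaps).
#' @export
match_classes <- function(gt, ar) {
  stopifnot(all(dim(gt) == dim(ar)))
  gcl <- sort(setdiff(unique(as.vector(gt)), 0L))
  acl <- sort(setdiff(unique(as.vector(ar)), 0L))
  ov <- matrix(0, length(gcl), length(acl),
               dimnames = list(gcl, acl))
  both <- gt > 0L & ar > 0L
  if (any(both)) {
    tab <- table(factor(gt[both], levels = gcl),
                 factor(ar[both], levels = acl))
    ov[] <- as.numeric(tab)
  }
  m <- rep(NA_integer_, length(gcl))
  names(m) <- gcl
  if (length(gcl) > 0L && length(acl) > 0L) {
    ng <- length(gcl); na <- length(acl)
    edges <- which(ov >= 0, arr.ind = TRUE)  # complete bipartite
    g <- igraph::make_bipartite_graph(
      c(rep(FALSE, ng), rep(TRUE, na)),
      edges = as.vector(t(cbind(edges[, 1], ng + edges[, 2]))))
    # small epsilon keeps zero-overlap edges admissible without changing
    # the argmax over total overlap
    igraph::E(g)$weight <- ov[edges] + 1e-9
    mt <- igraph::max_bipartite_match(g)$matching
    for (i in seq_len(ng)) {
      if (!is.na(mt[i])) m[i] <- acl[mt[i] - ng]
    }
  }
  list(gt_classes = gcl, ar_classes = acl, match = m, overlap = ov)
}

#' Segmentation accuracy and over/under-segmentation rates
#'
#' Over the K ground-truth classes (matched one-to-one to result
#' classes): \eqn{SA = (1/K)\sum |gt_i \cap ar_i| / |gt_i|};
#' \eqn{OR = (1/K)\sum (|ar_i| - |\cap|)/|gt_i| \epsilon(\cdot)};
#' \eqn{UR = (1/K)\sum (|gt_i| - |\cap|)/|gt_i| \epsilon(\cdot)}, with
#' \eqn{\epsilon(t) = 1} for t > 0 and 0 otherwise, all in pixels.
#'
#' @param gt,ar Label matrices.
#' @param matching Optional precomputed \code{\link{match_classes}}.
#' @return Named numeric vector (SA, OR, UR).
#' @export
sa_or_ur <- function(gt, ar, matching = NULL) {
  if (is.null(matching)) matching <- match_classes(gt, ar)
  gcl <- matching$gt_classes
  if (length(gcl) == 0L) stop("no ground-truth classes")
  sa <- or <- ur <- 0
  for (i in seq_along(gcl)) {
    gmask <- gt == gcl[i]
    g_n <- sum(gmask)
    if (g_n == 0L) {
      warning("ground-truth class ", gcl[i], " has zero pixels; excluded")
      next
    }
    a_id <- matching$match[i]
    if (is.na(a_id)) {
      a_n <- 0L
      inter <- 0L
    } else {
      amask <- ar == a_id
      a_n <- sum(amask)
      inter <- sum(gmask & amask)
    }
    sa <- sa + inter / g_n
    over <- a_n - inter
    under <- g_n - inter
    or <- or + over / g_n * (over > 0)
    ur <- ur + under / g_n * (under > 0)
  }
  k <- sum(vapply(gcl, function(g) sum(gt == g) > 0, logical(1)))
  c(SA = sa / k, OR = or / k, UR = ur / k)
}

#' Dice coefficient of two binary masks
#'
#' \eqn{2|\cap| / (|gt| + |ar|)}; defined as 1 when both masks are empty
#' (vacuous agreement).
#'
#' @param gt,ar Binary masks (any non-zero value counts).
#' @return Dice in [0, 1].
#' @export
dice <- function(gt, ar) {
  stopifnot(all(dim(gt) == dim(ar)))
  g <- gt > 0; a <- ar > 0
  denom <- sum(g) + sum(a)
  if (denom == 0L) return(1)
  2 * sum(g & a) / denom
}

#' Best Dice and symmetric best Dice over instance maps
#'
#' \eqn{BD(L^a, L^b) = (1/M) \sum_i \max_j Dice(L^a_i, L^b_j)} over the M
#' instances of the first map; \eqn{SBD = \min(BD(ar, gt), BD(gt, ar))}.
#' Background label 0 is excluded.
#'
#' @param a,b,ar,gt Instance label matrices.
#' @return Scalar in [0, 1].
#' @export
best_dice <- function(a, b) {
  acl <- setdiff(unique(as.vector(a)), 0L)
  bcl <- setdiff(unique(as.vector(b)), 0L)
  if (length(acl) == 0L) return(0)
  if (length(bcl) == 0L) return(0)
  na <- vapply(acl, function(i) sum(a == i), numeric(1))
  nb <- vapply(bcl, function(j) sum(b == j), numeric(1))
  both <- a > 0L & b > 0L
  tab <- matrix(0, length(acl), length(bcl))
  if (any(both)) {
    tt <- table(factor(a[both], levels = acl), factor(b[both], levels = bcl))
    tab[] <- as.numeric(tt)
  }
  dmat <- 2 * tab / outer(na, nb, `+`)
  mean(apply(dmat, 1L, max))
}

#' @rdname best_dice
#' @export
symmetric_best_dice <- function(ar, gt) {
  if (n_labels(ar) == 0L || n_labels(gt) == 0L) {
    warning("a map has zero instances; SBD = 0")
    return(0)
  }
  min(best_dice(ar, gt), best_dice(gt, ar))
}

#' Difference in instance count
#'
#' @param ar,gt Instance label matrices.
#' @return Named vector: \code{DiC} (signed, result minus ground truth)
#'   and \code{absDiC}.
#' @export
dic <- function(ar, gt) {
  d <- n_labels(ar) - n_labels(gt)
  c(DiC = d, absDiC = abs(d))
}

#' Modified Hausdorff distance between two point sets
#'
#' \eqn{D(A, B) = (1/|A|) \sum_{p \in A} \min_q ||p - q||};
#' \eqn{MHD = \max(D(A, B), D(B, A))}.
#'
#' @param a,b Numeric n x 2 point matrices (non-empty).
#' @return MHD (>= 0).
#' @export
mhd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty point set")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) - 2 * a %*% t(b) +
    outer(rep(1, nrow(a)), rowSums(b^2))
  d2[d2 < 0] <- 0
  dab <- mean(sqrt(apply(d2, 1L, min)))
  dba <- mean(sqrt(apply(d2, 2L, min)))
  max(dab, dba)
}

#' Boundary pixels of one region
#'
#' A region pixel is a boundary pixel when an 8-neighbour lies outside
#' the region or it sits on the image border.
#'
#' @param labels Label matrix.
#' @param id Region label.
#' @return n x 2 matrix of (row, col) positions, 0-based.
#' @export
region_boundary <- function(labels, id) {
  m <- labels == id
  h <- nrow(m); w <- ncol(m)
  inner <- m
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
      cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
      inner <- inner & m[rs, cs]
    }
  }
  onborder <- m
  if (h > 2 && w > 2) onborder[2:(h - 1), 2:(w - 1)] <- FALSE
  bd <- m & (!inner | onborder)
  idx <- which(bd, arr.ind = TRUE)
  cbind(idx[, 1] - 1, idx[, 2] - 1)
}

#' MHD between matched instances or plant masks
#'
#' Instance mode: instances are matched by maximum overlap
#' (\code{\link{match_classes}}) and the mean MHD over matched pairs is
#' returned. Binary mode (both maps 0/1): the MHD of the two mask
#' boundaries.
#'
#' @param ar,gt Label matrices.
#' @return Scalar MHD (pixels); NA when no pair is comparable.
#' @export
boundary_mhd <- function(ar, gt) {
  mt <- match_classes(gt, ar)
  vals <- numeric(0)
  for (i in seq_along(mt$gt_classes)) {
    a_id <- mt$match[i]
    if (is.na(a_id)) next
    pa <- region_boundary(gt, mt$gt_classes[i])
    pb <- region_boundary(ar, a_id)
    if (nrow(pa) == 0L || nrow(pb) == 0L) next
    vals <- c(vals, mhd(pa, pb))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Metric report over pairs of maps
#'
#' Computes per-image metrics and a mean (population standard deviation)
#' aggregate row. Semantic mode: SA, OR, UR and boundary MHD; instance
#' mode: FBD of the union masks, SBD, DiC, |DiC| and instance MHD.
#' Mismatched shapes are reported and the pair skipped.
#'
#' @param gt_list,ar_list Lists of label matrices, paired by position.
#' @param mode "semantic" or "instance".
#' @return Data frame, one row per scored pair plus an "aggregate" row
#'   (population sd rows appended as attributes \code{sd}).
#' @export
score_report <- function(gt_list, ar_list, mode = c("semantic", "instance")) {
  mode <- match.arg(mode)
  stopifnot(length(gt_list) == length(ar_list), length(gt_list) >= 1)
  rows <- list()
  for (i in seq_along(gt_list)) {
    gt <- gt_list[[i]]; ar <- ar_list[[i]]
    if (!all(dim(gt) == dim(ar))) {
      warning("pair ", i, ": shape mismatch, skipped")
      next
    }
    if (mode == "semantic") {
      v <- sa_or_ur(gt, ar)
      rows[[length(rows) + 1L]] <-
        data.frame(image = i, SA = v[["SA"]], OR = v[["OR"]],
                   UR = v[["UR"]], MHD = boundary_mhd(ar, gt))
    } else {
      d <- dic(ar, gt)
      rows[[length(rows) + 1L]] <-
        data.frame(image = i, FBD = dice(gt, ar),
                   SBD = symmetric_best_dice(ar, gt),
                   DiC = d[["DiC"]], absDiC = d[["absDiC"]],
                   MHD = boundary_mhd(ar, gt))
    }
  }
  if (length(rows) == 0L) stop("no scorable pairs")
  df <- do.call(rbind, rows)
  met <- setdiff(names(df), "image")
  agg <- df[1, , drop = FALSE]
  agg$image <- NA_integer_
  sds <- numeric(length(met))
  names(sds) <- met
  for (m in met) {
    x <- df[[m]][!is.na(df[[m]])]
    agg[[m]] <- mean(x)
    sds[m] <- sqrt(mean((x - mean(x))^2))  # population sd
  }
  out <- rbind(df, agg)
  rownames(out) <- c(seq_len(nrow(df)), "aggregate")
  attr(out, "sd") <- sds
  out
}
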