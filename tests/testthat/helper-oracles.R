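# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, explicit enumeration) and never share
# code with the implementation they check.

random_label_map <- function(h, w, k, p_bg = 0.2) {
  matrix(sample(0:k, h * w, replace = TRUE,
                prob = c(p_bg, rep((1 - p_bg) / k, k))), h, w)
}

# SA/OR/UR by explicit per-class pixel counting over a given matching
oracle_sa_or_ur <- function(gt, ar, match) {
  gcl <- sort(setdiff(unique(as.vector(gt)), 0L))
  sa <- or <- ur <- 0
  for (g in gcl) {
    gn <- 0; an <- 0; inter <- 0
    a <- match[[as.character(g)]]
    for (i in seq_len(nrow(gt))) {
      for (j in seq_len(ncol(gt))) {
        if (gt[i, j] == g) gn <- gn + 1
        if (!is.null(a) && !is.na(a) && ar[i, j] == a) {
          an <- an + 1
          if (gt[i, j] == g) inter <- inter + 1
        }
      }
    }
    sa <- sa + inter / gn
    if (an - inter > 0) or <- or + (an - inter) / gn
    if (gn - inter > 0) ur <- ur + (gn - inter) / gn
  }
  c(SA = sa, OR = or, UR = ur) / length(gcl)
}

oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] > 0) na <- na + 1
    if (b[i] > 0) nb <- nb + 1
    if (a[i] > 0 && b[i] > 0) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

oracle_best_dice <- function(a, b) {
  acl <- setdiff(unique(as.vector(a)), 0L)
  bcl <- setdiff(unique(as.vector(b)), 0L)
  if (length(acl) == 0 || length(bcl) == 0) return(0)
  total <- 0
  for (i in acl) {
    best <- 0
    for (j in bcl) {
      d <- oracle_dice((a == i) + 0L, (b == j) + 0L)
      if (d > best) best <- d
    }
    total <- total + best
  }
  total / length(acl)
}

oracle_mhd <- function(A, B) {
  dab <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
    dab <- dab + best
  }
  dba <- 0
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
    dba <- dba + best
  }
  max(dab / nrow(A), dba / nrow(B))
}

# best one-to-one matching by exhaustive search over permutations
oracle_match <- function(gt, ar) {
  gcl <- sort(setdiff(unique(as.vector(gt)), 0L))
  acl <- sort(setdiff(unique(as.vector(ar)), 0L))
  ov <- matrix(0, length(gcl), length(acl))
  for (i in seq_along(gcl)) {
    for (j in seq_along(acl)) {
      ov[i, j] <- sum(gt == gcl[i] & ar == acl[j])
    }
  }
  n <- max(length(gcl), length(acl))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -1
  best_m <- NULL
  for (p in perms(seq_len(n))) {
    tot <- 0
    for (i in seq_along(gcl)) {
      j <- p[i]
      if (i <= length(gcl) && j <= length(acl)) tot <- tot + ov[i, j]
    }
    if (tot > best) {
      best <- tot
      best_m <- p
    }
  }
  m <- rep(NA_integer_, length(gcl))
  names(m) <- gcl
  for (i in seq_along(gcl)) {
    if (best_m[i] <= length(acl)) m[i] <- acl[best_m[i]]
  }
  list(match = m, total = best)
}

# direct O(n^2) spatial convolution with the same folded-reflection
# boundary rule (true convolution: kernel flipped)
oracle_convolve <- function(ch, k) {
  h <- nrow(ch); w <- ncol(ch)
  rr <- (nrow(k) - 1) %/% 2; rc <- (ncol(k) - 1) %/% 2
  ref <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      s <- 0
      for (dr in -rr:rr) {
        for (dc in -rc:rc) {
          s <- s + k[rr + 1 - dr, rc + 1 - dc] *
            ch[ref(r + dr, h), ref(cc + dc, w)]
        }
      }
      out[r, cc] <- s
    }
  }
  out
}

make_joint_samples <- function(luv) {
  h <- dim(luv)[1]; w <- dim(luv)[2]
  cbind(as.vector(row(luv[, , 1])) - 1, as.vector(col(luv[, , 1])) - 1,
        as.vector(luv[, , 1]), as.vector(luv[, , 2]), as.vector(luv[, , 3]))
}

inside_disk_test <- function(h, w, r0, c0, rad) {
  dr <- outer(seq_len(h) - 1 - r0, rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - 1 - c0)
  dr * dr + dc * dc <= rad * rad
}
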