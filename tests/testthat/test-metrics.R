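test_that("class matching maximizes total overlap (exhaustive oracle)", {
  set.seed(41)
  for (rep in 1:20) {
    gt <- random_label_map(8, 8, 3)
    ar <- random_label_map(8, 8, 3)
    ours <- match_classes(gt, ar)
    oracle <- oracle_match(gt, ar)
    tot <- 0
    for (i in seq_along(ours$gt_classes)) {
      a <- ours$match[i]
      if (!is.na(a)) tot <- tot + sum(gt == ours$gt_classes[i] & ar == a)
    }
    expect_identical(tot, oracle$total)
  }
  # identity and permutation recovery
  gt <- matrix(rep(1:3, each = 4), 3, 4, byrow = TRUE)
  expect_identical(unname(match_classes(gt, gt)$match), 1:3)
  perm <- matrix(c(3L, 1L, 2L)[gt], 3, 4)
  expect_identical(unname(match_classes(gt, perm)$match), c(3L, 1L, 2L))
})

test_that("SA/OR/UR match the hand-counted example and identities", {
  # gt class of 10 px; ar covers 6 of them plus 2 outside
  gt <- matrix(0L, 4, 5)
  gt[1:2, 1:5] <- 1L
  ar <- matrix(0L, 4, 5)
  ar[1, 1:5] <- 1L
  ar[2, 1] <- 1L
  ar[3, 1:2] <- 1L
  v <- sa_or_ur(gt, ar)
  expect_equal(v[["SA"]], 0.6, tolerance = 1e-12)
  expect_equal(v[["OR"]], 0.2, tolerance = 1e-12)
  expect_equal(v[["UR"]], 0.4, tolerance = 1e-12)
  # perfect agreement
  expect_equal(unname(sa_or_ur(gt, gt)), c(1, 0, 0))
})

test_that("every metric equals its brute-force oracle on random maps", {
  set.seed(99)
  for (rep in 1:100) {
    h <- sample(4:16, 1); w <- sample(4:16, 1)
    k <- sample(2:4, 1)
    gt <- random_label_map(h, w, k)
    ar <- random_label_map(h, w, k)
    if (n_labels(gt) == 0 || n_labels(ar) == 0) next
    mt <- match_classes(gt, ar)
    ours <- sa_or_ur(gt, ar, mt)
    oracle <- oracle_sa_or_ur(gt, ar, as.list(mt$match))
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-12)
    expect_equal(dice(gt, ar), oracle_dice(gt, ar), tolerance = 1e-12)
    expect_equal(best_dice(ar, gt), oracle_best_dice(ar, gt),
                 tolerance = 1e-12)
    expect_equal(symmetric_best_dice(ar, gt),
                 min(oracle_best_dice(ar, gt), oracle_best_dice(gt, ar)),
                 tolerance = 1e-12)
    d <- dic(ar, gt)
    expect_identical(unname(d[["DiC"]]),
                     n_labels(ar) - n_labels(gt))
    A <- which(gt == 1, arr.ind = TRUE)
    B <- which(ar == 1, arr.ind = TRUE)
    if (nrow(A) > 0 && nrow(B) > 0) {
      expect_equal(mhd(A, B), oracle_mhd(A, B), tolerance = 1e-12)
    }
  }
})

test_that("metric directionality and bounds hold", {
  gt <- matrix(c(1L, 1L, 1L, 2L), 2, 2)  # instances of 3 and 1 pixels
  ar <- matrix(1L, 2, 2)                  # one instance covering all
  expect_equal(dice(gt, ar), dice(ar, gt))
  # BD(gt, ar) = mean(6/7, 2/5); BD(ar, gt) = max(6/7, 2/5)
  expect_equal(best_dice(gt, ar), mean(c(6 / 7, 2 / 5)), tolerance = 1e-12)
  expect_equal(best_dice(ar, gt), 6 / 7, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(best_dice(gt, ar), best_dice(ar, gt))))
  sbd <- symmetric_best_dice(ar, gt)
  expect_lte(sbd, best_dice(ar, gt))
  expect_lte(sbd, best_dice(gt, ar))
  # SBD invariant to relabeling
  relab <- matrix(7L, 2, 2)
  expect_equal(symmetric_best_dice(relab, gt), sbd)
  # Dice conventions
  e <- matrix(0L, 2, 2)
  expect_equal(dice(e, e), 1)
  expect_equal(dice(gt, e * 0L), 0)
  expect_equal(dice(matrix(c(1L, 1L, 0L, 0L), 1),
                    matrix(c(0L, 0L, 1L, 1L), 1)), 0)
  # |gt|=100, |ar|=50, overlap 50
  g2 <- matrix(0L, 10, 20); g2[, 1:10] <- 1L
  a2 <- matrix(0L, 10, 20); a2[, 6:10] <- 1L
  expect_equal(dice(g2, a2), 2 * 50 / 150, tolerance = 1e-12)
})

test_that("MHD obeys its defining cases", {
  expect_equal(mhd(cbind(0, 0), cbind(3, 4)), 5)
  p <- cbind(c(1, 2, 5), c(0, 2, 2))
  expect_equal(mhd(p, p), 0)
  expect_error(mhd(p[0, , drop = FALSE], p), "empty")
  # instance counts
  expect_identical(unname(dic(matrix(c(1L, 2L, 3L, 4L, 5L, 0L), 2),
                              matrix(c(1L, 2L, 3L, 0L, 0L, 0L), 2))),
                   c(2L, 2L))
})

test_that("region boundaries feed the instance-level MHD", {
  m <- matrix(0L, 8, 8)
  m[3:6, 3:6] <- 1L
  b <- region_boundary(m, 1L)
  # the 4x4 square has 12 boundary pixels
  expect_identical(nrow(b), 12L)
  expect_equal(boundary_mhd(m, m), 0)
})

test_that("score reports aggregate with population standard deviation", {
  g1 <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  rep1 <- score_report(list(g1), list(g1), mode = "instance")
  expect_identical(nrow(rep1), 2L)
  expect_equal(rep1$FBD[2], 1)
  expect_equal(unname(attr(rep1, "sd")["FBD"]), 0)

  # FBD 0.9 and 0.7 -> mean 0.8, sd 0.1 (constructed masks)
  gt <- matrix(0L, 1, 20); gt[1, 1:10] <- 1L
  a_9 <- matrix(0L, 1, 20); a_9[1, 1:9] <- 1L; a_9[1, 11] <- 1L  # inter 9
  # dice = 2*9/20 = 0.9
  a_7 <- matrix(0L, 1, 20); a_7[1, 1:7] <- 1L; a_7[1, 11:13] <- 1L
  # dice = 2*7/20 = 0.7
  r <- score_report(list(gt, gt), list(a_9, a_7), mode = "instance")
  expect_identical(nrow(r), 3L)
  expect_equal(r$FBD[3], 0.8, tolerance = 1e-12)
  expect_equal(unname(attr(r, "sd")["FBD"]), 0.1, tolerance = 1e-12)

  expect_warning(r2 <- score_report(list(gt, matrix(0L, 2, 2)),
                                    list(a_9, matrix(0L, 3, 3)),
                                    mode = "instance"),
                 "shape mismatch")
  expect_identical(nrow(r2), 2L)
})
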