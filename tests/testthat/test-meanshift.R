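test_that("Epanechnikov kernel and profile evaluate to their closed forms", {
  expect_equal(epanechnikov_profile(0.3), 0.7)
  expect_equal(epanechnikov_profile(1.2), 0)
  expect_equal(epanechnikov_kernel(0, 5), 3.5)
  expect_equal(epanechnikov_kernel(1, 5), 0)
  expect_equal(epanechnikov_shadow(c(0.5, 1.5)), c(1, 0))
  # normalized kernel integrates to 1 over the unit interval (d = 1)
  xs <- seq(-1, 1, length.out = 20001)
  vals <- epanechnikov_kernel(xs^2, 1, normalized = TRUE)
  integral <- sum(vals) * (xs[2] - xs[1])
  expect_equal(integral, 1, tolerance = 1e-4)
})

test_that("the KDE matches a direct sum and peaks at symmetric centres", {
  set.seed(19)
  x <- matrix(rnorm(50), 50, 1)
  h <- 0.8
  f <- kde(0.3, x, h)
  direct <- sum(sapply(x, function(xi) {
    u2 <- ((xi - 0.3) / h)^2
    if (u2 <= 1) 0.75 * (1 - u2) else 0
  })) / (50 * h)
  expect_equal(f, direct, tolerance = 1e-12)
  # single sample at the evaluation point: c_{k,d} / h^d
  expect_equal(kde(0, matrix(0, 1, 1), 2), 0.75 / 2, tolerance = 1e-12)
  # two symmetric points: maximal at the midpoint
  s2 <- matrix(c(-0.5, 0.5), 2, 1)
  expect_gt(kde(0, s2, 1), kde(0.3, s2, 1))
  expect_gt(kde(0, s2, 1), kde(-0.3, s2, 1))
})

test_that("a shift step is the plain mean of the joint window", {
  set.seed(23)
  samples <- cbind(runif(20, 0, 10), runif(20, 0, 10),
                   rnorm(20, 50, 10), rnorm(20, 0, 10), rnorm(20, 0, 10))
  y <- samples[7, ]
  st <- mean_shift_step(y, samples, h_s = 4, h_r = 15)
  keep <- (samples[, 1] - y[1])^2 + (samples[, 2] - y[2])^2 <= 16 &
    (samples[, 3] - y[3])^2 + (samples[, 4] - y[4])^2 +
      (samples[, 5] - y[5])^2 <= 225
  expect_equal(as.numeric(st), colMeans(samples[keep, , drop = FALSE]),
               tolerance = 1e-12)

  # all candidates identical to y: fixed point
  same <- matrix(rep(y, 5), 5, byrow = TRUE)
  expect_equal(as.numeric(mean_shift_step(y, same, 4, 15)), y)

  # two spatially symmetric candidates with equal colours: midpoint
  pair <- rbind(c(1, 0, 10, 0, 0), c(3, 0, 10, 0, 0))
  st2 <- mean_shift_step(c(2, 0, 10, 0, 0), pair, 4, 15)
  expect_equal(st2[1], 2)

  # empty window flag
  far <- matrix(c(100, 100, 0, 0, 0), 1)
  st3 <- mean_shift_step(c(0, 0, 0, 0, 0), far, 1, 1)
  expect_true(attr(st3, "empty"))
})

test_that("mode search converges and ascends the density", {
  sc <- make_blob_scene(20, 20, 1, noise_sd = 0, seed = 1)
  luv <- rgb_to_luv(sc$image)
  samples <- make_joint_samples(luv)
  fm <- find_mode(samples[25, ], samples, h_s = 3, h_r = 10)
  # constant image: converges immediately, colour unchanged
  expect_true(fm$converged)
  expect_equal(fm$mode[3:5], samples[25, 3:5], tolerance = 1e-9)

  set.seed(2)
  sc2 <- make_blob_scene(24, 24, 2, noise_sd = 4, seed = 5)
  luv2 <- rgb_to_luv(sc2$image)
  s2 <- make_joint_samples(luv2)
  for (i in c(1, 100, 400)) {
    fm2 <- find_mode(s2[i, ], s2, h_s = 5, h_r = 20)
    kv <- apply(fm2$trajectory, 1, function(p) {
      msbslda:::kde_joint(p, s2, 5, 20)
    })
    expect_true(all(diff(kv) >= -1e-12))
    expect_gte(kv[length(kv)], kv[1])
  }
})

test_that("filtering reduces within-region variance and is near-idempotent", {
  sc <- make_blob_scene(32, 32, 2, noise_sd = 5, seed = 9)
  luv <- rgb_to_luv(sc$image)
  ms <- filter_image(luv, h_s = 4, h_r = 20, thr = 0.1)
  for (k in 1:2) {
    m <- sc$gt_regions == k
    v_before <- sum(vapply(1:3, function(ch) var(luv[, , ch][m]), 0))
    v_after <- sum(vapply(1:3, function(ch) var(ms$filtered[, , ch][m]), 0))
    expect_lt(v_after, v_before)
  }
  # constant image unchanged
  sc0 <- make_blob_scene(16, 16, 1, noise_sd = 0, seed = 1)
  luv0 <- rgb_to_luv(sc0$image)
  ms0 <- filter_image(luv0, 4, 20)
  expect_equal(ms0$filtered, luv0, tolerance = 1e-9)
  # a second pass moves colours far less than the first (near-idempotence)
  ms2 <- filter_image(ms$filtered, h_s = 4, h_r = 20, thr = 0.1)
  d1 <- sqrt(apply((ms$filtered - luv)^2, c(1, 2), sum))
  d2 <- sqrt(apply((ms2$filtered - ms$filtered)^2, c(1, 2), sum))
  expect_lt(mean(d2), 0.15 * mean(d1))
  expect_gt(mean(d2 < 0.5), 0.8)
})

test_that("C++ filtering equals the plain-R mode search", {
  sc <- make_blob_scene(16, 16, 2, noise_sd = 3, seed = 4)
  luv <- rgb_to_luv(sc$image)
  samples <- make_joint_samples(luv)
  ms <- filter_image(luv, h_s = 4, h_r = 15, thr = 0.1, s_thr = 0.5,
                     max_iter = 100)
  for (i in c(3, 77, 200, 256)) {
    fm <- find_mode(samples[i, ], samples, 4, 15, thr = 0.1, s_thr = 0.5,
                    max_iter = 100)
    expect_equal(as.numeric(ms$modes[i, ]), fm$mode, tolerance = 1e-9)
  }
})

test_that("mode clustering separates blobs and respects min_size", {
  sc <- make_blob_scene(32, 32, 2, noise_sd = 2, seed = 3)
  luv <- rgb_to_luv(sc$image)
  ms <- filter_image(luv, 4, 20)
  cl <- cluster_modes(ms, 4, 20, min_size = 10)
  expect_identical(sort(unique(as.vector(cl$cluster))),
                   seq_len(cl$n_clusters))
  expect_true(all(cl$sizes >= 10))
  # the two dominant clusters coincide with the two regions
  top2 <- order(-cl$sizes)[1:2]
  agree <- max(mean((cl$cluster %in% top2[1]) == (sc$gt_regions == 1)),
               mean((cl$cluster %in% top2[2]) == (sc$gt_regions == 1)))
  expect_gt(agree, 0.9)
  # all modes identical -> one cluster
  flat <- matrix(rep(c(1, 1, 10, 0, 0), 9), 9, byrow = TRUE)
  cl1 <- cluster_modes(flat, 4, 20, min_size = 1, dim_hw = c(3, 3))
  expect_identical(cl1$n_clusters, 1L)
  # cluster count is non-increasing in min_size
  ns <- vapply(c(1, 10, 50), function(msz) {
    cluster_modes(ms, 4, 20, min_size = msz)$n_clusters
  }, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("cluster count is non-increasing as h_r grows", {
  sc <- make_blob_scene(32, 32, 3, noise_sd = 6, seed = 12)
  luv <- rgb_to_luv(sc$image)
  ns <- vapply(c(5, 10, 20, 40), function(hr) {
    ms <- filter_image(luv, 4, hr)
    cluster_modes(ms, 4, hr, min_size = 5)$n_clusters
  }, 0L)
  expect_true(all(diff(ns) <= 0))
})
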