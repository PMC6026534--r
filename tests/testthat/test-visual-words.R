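test_that("the filter bank has the documented 17-filter layout", {
  bank <- filter_bank()
  expect_length(bank, 17L)
  fam <- vapply(bank, `[[`, "", "family")
  sig <- vapply(bank, `[[`, 0, "sigma")
  ch <- vapply(bank, function(b) as.integer(b$channel), 0L)
  expect_identical(fam, c(rep("gaussian", 9), rep("log", 4),
                          rep("dx", 2), rep("dy", 2)))
  expect_identical(sig[1:9], rep(c(1, 2, 4), each = 3))
  expect_identical(ch[1:9], rep(1:3, times = 3))
  expect_identical(sig[10:13], c(1, 2, 4, 8))
  expect_true(all(ch[10:17] == 1L))
  expect_identical(sig[14:17], c(2, 4, 2, 4))
})

test_that("responses behave linearly on degenerate inputs", {
  lab <- array(rep(c(40, 10, -5), each = 64), dim = c(8, 8, 3))
  r <- compute_responses(lab)
  # Gaussians reproduce the channel constant, zero-sum filters vanish
  expect_equal(r[4, 4, 1], 40, tolerance = 1e-10)
  expect_equal(r[4, 4, 2], 10, tolerance = 1e-10)
  expect_lt(max(abs(r[, , 10:17])), 1e-10)

  # impulse response of the sigma = 1 Gaussian at the centre
  lab2 <- array(0, dim = c(9, 9, 3))
  lab2[5, 5, 1] <- 1
  r2 <- compute_responses(lab2)
  k <- msbslda:::gaussian_kernel(1)
  expect_equal(r2[5, 5, 1], k[4, 4], tolerance = 1e-12)

  expect_error(compute_responses(array(0, c(1, 5, 3))), "too small")
})

test_that("responses equal direct spatial convolution on a random image", {
  set.seed(31)
  lab <- array(rnorm(16 * 16 * 3, 50, 12), dim = c(16, 16, 3))
  r <- compute_responses(lab)
  bank <- filter_bank()
  for (f in c(2, 11, 13, 14, 17)) {
    expect_equal(r[, , f],
                 oracle_convolve(lab[, , bank[[f]]$channel],
                                 bank[[f]]$kernel),
                 tolerance = 1e-9)
  }
})

test_that("patch descriptors are block means over the grid", {
  set.seed(8)
  resp <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  pd <- extract_patch_descriptors(resp, 4, 4)
  expect_identical(unname(pd$grid), c(2L, 2L))
  expect_identical(nrow(pd$descriptors), 4L)
  # hand block means, patch enumeration column-major
  for (ci in 1:2) {
    for (ri in 1:2) {
      id <- (ci - 1) * 2 + ri
      rows <- ((ri - 1) * 4 + 1):(ri * 4)
      cols <- ((ci - 1) * 4 + 1):(ci * 4)
      hand <- vapply(1:3, function(f) mean(resp[rows, cols, f]), 0)
      expect_equal(pd$descriptors[id, ], hand, tolerance = 1e-12)
    }
  }
  # patch_size 1, stride 1 reduces to per-pixel responses
  pd1 <- extract_patch_descriptors(resp, 1, 1)
  expect_equal(pd1$descriptors[, 2], as.vector(resp[, , 2]))
  # constant raster gives identical descriptors
  pdc <- extract_patch_descriptors(array(3, dim = c(8, 8, 2)), 4, 4)
  expect_true(all(pdc$descriptors == 3))
  # partial border patches: 10 rows with stride 4 -> ceiling(10/4) = 3 rows
  pdb <- extract_patch_descriptors(array(1, dim = c(10, 10, 1)), 4, 4)
  expect_identical(unname(pdb$grid), c(3L, 3L))
})

test_that("k-means dictionary recovers well-separated clusters", {
  set.seed(12)
  centers_true <- matrix(c(rep(0, 17), rep(10, 17), rep(-10, 17)), 3,
                         byrow = TRUE)
  x <- centers_true[rep(1:3, each = 50), ] + rnorm(150 * 17, sd = 0.2)
  d <- learn_dictionary(x, 3, seed = 5)
  # each true centre is near some learned centre
  for (k in 1:3) {
    dist <- sqrt(rowSums((d$centers - matrix(centers_true[k, ], 3, 17,
                                             byrow = TRUE))^2))
    expect_lt(min(dist), 0.5)
  }
  expect_identical(learn_dictionary(x, 3, seed = 5),
                   learn_dictionary(x, 3, seed = 5))
  # n_words == #descriptors: every descriptor its own centre
  xs <- matrix(rnorm(5 * 17), 5)
  ds <- learn_dictionary(xs, 5, seed = 1)
  expect_equal(sort(quantize(xs, ds)), 1:5)
  # degenerate identical descriptors warn
  expect_warning(learn_dictionary(matrix(1, 10, 17), 3, seed = 1),
                 "distinct")
})

test_that("quantization is the exact nearest-centre map with low-index ties", {
  set.seed(3)
  d <- list(centers = matrix(rnorm(6 * 17), 6), n_words = 6L)
  expect_identical(quantize(d$centers[3, , drop = FALSE], d), 3L)
  # equidistant descriptor: lowest index wins
  d2 <- list(centers = rbind(c(1, rep(0, 16)), c(-1, rep(0, 16))),
             n_words = 2L)
  expect_identical(quantize(matrix(0, 1, 17), d2), 1L)
  # brute-force scan agreement
  x <- matrix(rnorm(100 * 17), 100)
  w <- quantize(x, d)
  brute <- apply(x, 1, function(v) {
    which.min(colSums((t(d$centers) - v)^2))
  })
  expect_identical(w, unname(brute))
  expect_error(quantize(matrix(0, 1, 5), d), "dimension")
  # idempotence: quantizing the centres returns 1..N
  expect_identical(quantize(d$centers, d), 1:6)
})

test_that("word frequencies count and order correctly", {
  wf <- word_frequency(c(1L, 1L, 2L))
  expect_identical(wf$word, c(1L, 2L))
  expect_identical(wf$count, c(2L, 1L))
  set.seed(2)
  w <- sample(1:9, 500, TRUE)
  wf2 <- word_frequency(w)
  expect_identical(sum(wf2$count), 500L)
  expect_true(all(diff(wf2$count) <= 0))
  # order-invariance
  expect_identical(word_frequency(rev(w)), wf2)
  # top-word proportion of a uniform corpus near 1/5
  set.seed(4)
  wu <- sample(1:5, 1e4, TRUE)
  top <- word_frequency(wu)$count[1] / 1e4
  expect_lt(abs(top - 0.2), qbinom(0.995, 1e4, 0.2) / 1e4 - 0.2 + 0.01)
})
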