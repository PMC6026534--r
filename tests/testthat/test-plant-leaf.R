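test_that("plant extraction finds the green topic and rejects bare scenes", {
  p <- make_plant_scene(96, 96, 4, seed = 2)
  fg <- extract_plant(p$image, K = 2, seed = 2)
  expect_gte(dice(p$gt_regions == 2L, fg), 0.9)

  # an all-background scene has no green-dominant topic
  bare <- make_blob_scene(64, 64, 2,
                          colors = matrix(c(120, 90, 60, 90, 70, 120),
                                          2, 3, byrow = TRUE),
                          noise_sd = 5, seed = 3)
  expect_error(extract_plant(bare$image, K = 2, seed = 3),
               "no green-dominant topic")
})

test_that("moss is separated from the plant with a third topic", {
  pm <- make_plant_scene(96, 96, 4, moss = TRUE, seed = 5)
  fg <- extract_plant(pm$image, K = 3, seed = 5)
  expect_gte(mean(fg[pm$gt_regions == 4L] == 0), 0.9)
  expect_gte(dice(pm$gt_regions == 2L, fg), 0.85)
})

test_that("fruit removal splits the foreground cleanly and guards fruitless plants", {
  p <- make_plant_scene(128, 128, 5, fruit_count = 2, seed = 9)
  fgt <- ((p$gt_regions == 2L) | (p$gt_regions == 3L)) + 0L
  fr <- remove_fruit(p$image, fgt)
  expect_gte(mean(fr$fruit_mask[p$fruit_mask == 1L] == 1L), 0.99)
  expect_lte(mean(fr$fruit_mask[p$gt_regions == 2L] == 1L), 0.01)
  # partition of the foreground
  expect_true(all(fr$fruit_mask + fr$leaf_mask == fgt))

  pf <- make_plant_scene(128, 128, 5, fruit_count = 0, seed = 9)
  fr0 <- remove_fruit(pf$image, (pf$gt_regions == 2L) + 0L)
  expect_lt(sum(fr0$fruit_mask) / sum(pf$gt_regions == 2L), 0.005)
  expect_true(is.na(fr0$threshold))
  expect_error(remove_fruit(p$image, matrix(0L, 128, 128)), "empty")
})

test_that("the illumination report reproduces constructed cases and a brute-force count", {
  r1 <- illumination_check(matrix(130L, 50, 50))
  expect_equal(r1$alpha_prime, 1)
  expect_identical(r1$decision, "even")

  g <- matrix(c(rep(40L, 1250), rep(220L, 1250)), 50, 50)
  r2 <- illumination_check(g, beta_prime = 0.2)
  expect_equal(r2$alpha_prime, 0.5)
  expect_identical(r2$decision, "uneven")
  expect_equal(r2$R_s, 25.5)

  # brute-force per-pixel counting oracle at the reported M_s
  set.seed(77)
  gr <- matrix(sample(0:255, 900, TRUE), 30, 30)
  rep_ <- illumination_check(gr)
  vals <- gr[gr > 0]
  inwin <- sum(abs(vals - rep_$M_s) <= rep_$R_s)
  expect_equal(rep_$alpha_prime, inwin / length(vals), tolerance = 1e-12)

  expect_error(illumination_check(matrix(0L, 4, 4)), "no foreground")
})

test_that("homomorphic correction flattens a ramp and preserves flats", {
  flat <- matrix(120, 32, 32)
  expect_true(all(homomorphic_correct(flat) == 120L))

  set.seed(3)
  base <- matrix(rnorm(64 * 64, 120, 6), 64, 64)
  ramp <- sweep(base, 2, seq(0.6, 1.4, length.out = 64), `*`)
  corrected <- homomorphic_correct(ramp)
  ratio_in <- mean(ramp[, 1:32]) / mean(ramp[, 33:64])
  ratio_out <- mean(corrected[, 1:32]) / mean(corrected[, 33:64])
  expect_lt(abs(ratio_out - 1), abs(ratio_in - 1))
  expect_gte(min(corrected), 0)
  expect_lte(max(corrected), 255)
})

test_that("edge detection recalls leaf rims and stays inside the mask", {
  p <- make_plant_scene(96, 96, 4, noise_sd = 2, seed = 6)
  gt <- p$gt_leaves
  mask <- (gt > 0L) + 0L
  gray <- msbslda:::rgb_to_gray(p$image)
  gray[mask == 0L] <- 0L
  edges <- detect_strong_edges(gray, mask)
  # gt rim pixels (leaf-leaf boundaries)
  rim <- matrix(FALSE, 96, 96)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    rs <- pmin(pmax(seq_len(96) + d[1], 1), 96)
    cs <- pmin(pmax(seq_len(96) + d[2], 1), 96)
    nb <- gt[rs, cs]
    rim <- rim | (gt > 0L & nb > 0L & nb != gt)
  }
  if (any(rim)) {
    dist_to_edge <- t(EBImage::imageData(EBImage::distmap(
      EBImage::Image(t(edges == 0L)))))
    expect_gte(mean(dist_to_edge[rim] <= 2), 0.8)
  }
  expect_true(all(edges[mask == 0L] == 0L))
  # constant image: no edges
  expect_identical(sum(detect_strong_edges(matrix(100, 20, 20),
                                           matrix(1L, 20, 20))), 0L)
  # external map path
  ext <- matrix(0, 96, 96); ext[40, ] <- 1
  e2 <- detect_strong_edges(gray, mask, detector = "external",
                            external = ext)
  expect_true(all(e2[40, ] == (mask[40, ] > 0)))
  expect_error(detect_strong_edges(gray, mask, detector = "external",
                                   external = matrix(0, 5, 5)), "mismatch")
})

test_that("centroid location finds disk centres and respects min_distance", {
  mask <- matrix(0L, 64, 64)
  mask[inside_disk_test(64, 64, 31.5, 31.5, 20)] <- 1L
  ct <- locate_centroids(mask, NULL, min_distance = 5, dilation_radius = 5)
  expect_identical(nrow(ct), 1L)
  expect_lt(sqrt(sum((ct[1, ] - c(31.5, 31.5))^2)), 2.5)

  # two disks joined only through a 1-px edge line get split
  mask2 <- matrix(0L, 64, 96)
  mask2[inside_disk_test(64, 96, 31.5, 25, 16)] <- 1L
  mask2[inside_disk_test(64, 96, 31.5, 65, 16)] <- 1L
  edge <- matrix(0L, 64, 96)
  edge[, 45] <- 1L
  ct2 <- locate_centroids(mask2, edge, min_distance = 5,
                          dilation_radius = 5)
  expect_identical(nrow(ct2), 2L)

  # min_distance above the radius: nothing qualifies
  expect_warning(
    ct3 <- locate_centroids(mask, NULL, min_distance = 30,
                            dilation_radius = 5),
    "no distance-map maxima")
  expect_identical(nrow(ct3), 0L)
  expect_error(locate_centroids(matrix(0L, 4, 4)), "empty")
})

test_that("marker watershed partitions the mask around the seeds", {
  mask <- matrix(0L, 64, 96)
  mask[inside_disk_test(64, 96, 31.5, 30, 18)] <- 1L
  mask[inside_disk_test(64, 96, 31.5, 58, 18)] <- 1L
  ws <- watershed_leaves(mask, rbind(c(31.5, 30), c(31.5, 58)))
  inst <- ws$instances
  expect_identical(n_labels(inst), 2L)
  expect_true(all((inst > 0L) == (mask > 0L)))
  # each seed sits in its own instance
  expect_identical(inst[32, 31], 1L)
  expect_identical(inst[32, 59], 2L)
  # areas within 25% of each disk's own area
  a1 <- sum(inside_disk_test(64, 96, 31.5, 30, 18))
  for (i in 1:2) {
    expect_lt(abs(sum(inst == i) - a1) / a1, 0.25)
  }
  # single centroid: whole mask one instance
  ws1 <- watershed_leaves(mask, rbind(c(31.5, 30)))
  expect_identical(n_labels(ws1$instances), 1L)
  expect_true(all((ws1$instances > 0L) == (mask > 0L)))
})

test_that("the full leaf chain honours its contracts end to end", {
  p <- make_plant_scene(128, 128, 5, fruit_count = 2, seed = 9)
  res <- segment_leaves(p$image, K = 2, seed = 9)
  # every instance contains its seeding centroid
  cc <- cbind(pmin(pmax(round(res$centroids[, 1]) + 1, 1), 128),
              pmin(pmax(round(res$centroids[, 2]) + 1, 1), 128))
  expect_identical(n_labels(res$instances), nrow(res$centroids))
  expect_identical(sort(unique(res$instances[cc])),
                   seq_len(nrow(res$centroids)))
  # no instance overlaps the fruit by more than 5%
  for (i in seq_len(n_labels(res$instances))) {
    ov <- sum(res$instances == i & p$fruit_mask == 1L) /
      sum(res$instances == i)
    expect_lte(ov, 0.05)
  }
  # even-illumination scene skips the homomorphic branch
  expect_false(res$illumination$decision == "even" &&
                 res$illumination$corrected)
  # bit-reproducibility
  res2 <- segment_leaves(p$image, K = 2, seed = 9)
  expect_identical(res$instances, res2$instances)
})
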