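# Morlet power, baseline correction, condition segmentation, cluster
# permutation statistics, source contrast and voxel clustering.

test_that("Morlet power follows the amplitude-squared law and peaks at the carrier", {
  fs <- 250
  t <- seq(0, 2, by = 1 / fs)
  x1 <- matrix(sin(2 * pi * 10 * t), 1)
  tf1 <- morlet_power(x1, "alpha", sfreq = fs, times_s = t)
  tf2 <- morlet_power(2 * x1, "alpha", sfreq = fs, times_s = t)
  mid <- 150:350
  expect_equal(mean(tf2$power[1, 1, 3, mid]) / mean(tf1$power[1, 1, 3, mid]), 4)
  expect_equal(tf1$freqs[which.max(apply(tf1$power[1, 1, , mid], 1, mean))], 10)
  # zero signal -> zero power; white noise roughly flat across the band
  expect_equal(max(morlet_power(matrix(0, 1, 501), "theta", sfreq = fs,
                                times_s = t)$power), 0)
  set.seed(5)
  xw <- matrix(stats::rnorm(fs * 40), 1)
  tfw <- morlet_power(xw, "alpha", sfreq = fs, times_s = (0:(fs * 40 - 1)) / fs)
  bandmean <- apply(tfw$power[1, 1, , ], 1, mean)
  expect_lt(diff(range(bandmean)) / mean(bandmean), 0.5)
  expect_error(morlet_power(matrix(0, 1, 100), "theta", sfreq = fs,
                            times_s = (0:99) / fs), "too short")
})

test_that("decibel baseline correction matches the power change", {
  fs <- 250
  t <- seq(-1, 2, by = 1 / fs)
  amp <- ifelse(t < 0, 1, sqrt(2))              # power doubles after t = 0
  x <- matrix(amp * sin(2 * pi * 10 * t), 1)
  tf <- morlet_power(x, "alpha", sfreq = fs, times_s = t)
  tfb <- baseline_correct(tf, c(-0.75, -0.25))
  expect_equal(mean(tfb$power[1, 1, 3, t > 0.5 & t < 1.5]), 10 * log10(2),
               tolerance = 0.02)
  expect_equal(mean(tfb$power[1, 1, 3, t > -0.7 & t < -0.3]), 0, tolerance = 0.05)
  zero <- morlet_power(matrix(0, 1, length(t)), "alpha", sfreq = fs, times_s = t)
  expect_error(baseline_correct(zero, c(-0.75, 0)), "baseline")
  expect_error(baseline_correct(tf, c(-9, -8)), "outside")
})

test_that("condition segmentation yields the stated window lengths", {
  fs <- 250
  t <- seq(0, 12, by = 1 / fs)
  tf <- morlet_power(matrix(stats::rnorm(length(t)), 1), 5, sfreq = fs, times_s = t)
  first <- segment_conditions(tf, task = 1, random_onset_s = 0.5,
                              constant_onset_s = 5, interval = "first")
  expect_equal(dim(first$random$power)[4], dim(first$constant$power)[4])
  expect_equal(dim(first$random$power)[4] / fs, 0.5, tolerance = 0.02)
  second <- segment_conditions(tf, task = 1, random_onset_s = 0.5,
                               constant_onset_s = 5, interval = "second")
  expect_equal(dim(second$random$power)[4] / fs, 2.5, tolerance = 0.01)
  expect_equal(dim(second$constant$power)[4] / fs, 2.5, tolerance = 0.01)
  occ <- segment_conditions(tf, task = 2, trial_duration_s = 12)
  expect_equal(dim(occ$occluded$power)[4], dim(occ$visible$power)[4])
  # first visible window covers 0-2 s
  expect_lt(occ$visible$times_s[1], 0.01)
  expect_equal(occ$occluded$times_s[1], 2, tolerance = 0.01)
})

test_that("identical conditions produce no clusters; effects are localized", {
  mont <- make_montage(16)
  adj <- channel_adjacency(mont)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  set.seed(23)
  a <- array(stats::rnorm(12 * 16 * 50), c(12, 16, 50))
  expect_length(cluster_permutation_test(a, a, adj, n_permutations = 100), 0)
  b <- a
  b[, 1:6, 15:35] <- b[, 1:6, 15:35] - 2      # strong focal effect
  cl <- cluster_permutation_test(a, b, adj, n_permutations = 500, seed = 3,
                                 times_s = (0:49) / 250)
  expect_gt(length(cl), 0)
  best <- cl[[which.min(vapply(cl, `[[`, numeric(1), "p"))]]
  expect_lt(best$p, 0.05)
  expect_equal(best$polarity, "positive")
  expect_gt(length(intersect(best$channels, 1:6)), 3)
  # t_sum equals the brute-force sum over member points
  tfield <- attr(cl, "t_obs")
  brute <- sum(apply(best$members, 1, function(r) tfield[r["channel"], r["freq"], r["time"]]))
  expect_equal(best$t_sum, brute)
  expect_equal(best$t_sum, sum(best$members$t))
})

test_that("cluster p-values are invariant to adjacency-preserving channel relabeling", {
  mont <- make_montage(12)
  adj <- channel_adjacency(mont)
  set.seed(31)
  a <- array(stats::rnorm(10 * 12 * 30), c(10, 12, 30))
  b <- a
  b[, 3:7, 10:20] <- b[, 3:7, 10:20] + 1.8
  perm <- sample(12)
  cl1 <- cluster_permutation_test(a, b, adj, n_permutations = 300, seed = 7)
  cl2 <- cluster_permutation_test(a[, perm, ], b[, perm, ], adj[perm, perm],
                                  n_permutations = 300, seed = 7)
  expect_equal(sort(vapply(cl1, `[[`, numeric(1), "p")),
               sort(vapply(cl2, `[[`, numeric(1), "p")))
  expect_equal(sort(vapply(cl1, `[[`, numeric(1), "t_sum")),
               sort(vapply(cl2, `[[`, numeric(1), "t_sum")))
})

test_that("the normalized contrast is bounded, antisymmetric and handles zeros", {
  expect_equal(as.numeric(normalized_contrast(c(1, 2, 0), c(1, 1, 0))),
               c(0, 1 / 3, 0))
  expect_equal(as.numeric(normalized_contrast(c(5, 0), c(0, 0))), c(1, 0))
  set.seed(3)
  p1 <- stats::runif(50); p2 <- stats::runif(50)
  r <- normalized_contrast(p1, p2)
  expect_equal(as.numeric(r), -as.numeric(normalized_contrast(p2, p1)))
  expect_true(all(abs(r) <= 1))
  expect_equal(attr(normalized_contrast(c(0, 1), c(0, 1)), "n_zero_sum"), 1L)
  expect_error(normalized_contrast(1:3, 1:2), "mismatch")
})

test_that("density-based voxel clustering separates blobs and labels noise", {
  # grid of voxels, 5 mm edge
  g <- expand.grid(x = seq(0, 45, 5), y = seq(0, 45, 5), z = 0)
  ratio <- rep(0, nrow(g))
  blob1 <- which(g$x <= 10 & g$y <= 10)
  ratio[blob1] <- 0.9
  res1 <- dbscan_voxel_clusters(g, ratio, 5, tail_fraction = length(blob1) / nrow(g),
                                min_pts = 5)
  expect_length(res1$clusters, 1)
  expect_setequal(res1$clusters[[1]]$members, blob1)
  blob2 <- which(g$x >= 35 & g$y >= 35)
  ratio[blob2] <- 0.8
  res2 <- dbscan_voxel_clusters(g, ratio,
                                5, tail_fraction = (length(blob1) + length(blob2)) / nrow(g),
                                min_pts = 4)
  expect_length(res2$clusters, 2)
  # scattered extreme voxels below the density threshold -> all noise
  scat <- c(1, 40, 80, 55, 99)
  ratio3 <- rep(0, nrow(g)); ratio3[scat] <- 1
  res3 <- dbscan_voxel_clusters(g, ratio3, 5, tail_fraction = 0.05, min_pts = 5)
  expect_true(all(res3$labels == 0))
  expect_error(dbscan_voxel_clusters(g[0, ], numeric(0), 5), "empty|length")
})
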