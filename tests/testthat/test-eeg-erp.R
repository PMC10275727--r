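# Peak-locked epoching, CSD, weighting, ERP cluster statistics, cluster
# selection, peak latency and the vincentile-bin matrix.

make_eeg <- function(nch = 16, dur = 60, sfreq = 250, sd = 1, seed = 1) {
  set.seed(seed)
  list(data = matrix(stats::rnorm(nch * dur * sfreq, sd = sd), nch),
       sfreq = sfreq, t0 = 0, montage = make_montage(nch))
}

test_that("epoching cuts 313-sample baseline-corrected epochs", {
  eeg <- make_eeg(4, dur = 30)
  eeg$data[2, ] <- 7                       # constant channel
  peaks <- c(2, 5.5, 10, 29.9)             # last one too close to the edge
  eps <- epoch_around_peaks(eeg, peaks)
  expect_equal(dim(eps$data), c(3, 4, 313))
  expect_equal(attr(eps, "n_skipped"), 1L)
  expect_equal(max(abs(eps$data[, 2, ])), 0)   # constant -> zero after baseline
  expect_equal(range(eps$times_s), c(-0.5, 187 / 250))
  expect_error(epoch_around_peaks(eeg, 1000), "no peak")
})

test_that("CSD maps uniform topographies to zero and is linear", {
  mont <- make_montage(20)
  tvec <- (0:9) / 250
  uni <- epoch_set(array(3.3, c(1, 20, 10)), tvec, 250, mont)
  expect_lt(max(abs(csd_transform(uni)$data)), 1e-9)
  set.seed(9)
  x <- array(stats::rnorm(2 * 20 * 10), c(2, 20, 10))
  y <- array(stats::rnorm(2 * 20 * 10), c(2, 20, 10))
  cx <- csd_transform(epoch_set(x, tvec, 250, mont))$data
  cy <- csd_transform(epoch_set(y, tvec, 250, mont))$data
  cxy <- csd_transform(epoch_set(2 * x - 5 * y, tvec, 250, mont))$data
  expect_equal(cxy, 2 * cx - 5 * cy, tolerance = 1e-8)
  expect_error(csd_transform(epoch_set(x[, 1:8, , drop = FALSE], tvec, 250,
                                       mont[1:8, ])), "16 channels")
})

test_that("CSD of a focal topography shows a centre-surround pattern", {
  mont <- make_montage(40)
  pos <- as.matrix(mont[, c("x", "y", "z")])
  centre <- 1
  ang <- acos(pmin(1, pos %*% pos[centre, ]))
  topo <- exp(-(ang / 0.5)^2)              # Gaussian bump at the centre channel
  eps <- epoch_set(array(topo, c(1, 40, 1)), 0, 250, mont)
  csd <- drop(csd_transform(eps)$data)
  expect_gt(csd[centre], 0)
  ring <- which(ang > 0.5 & ang < 1.2)
  expect_lt(mean(csd[ring]), 0)            # sign reversal in the surround
})

test_that("trial-count weights normalize to the median", {
  expect_equal(weight_by_trial_count(c(100, 100, 100)), c(1, 1, 1))
  expect_equal(weight_by_trial_count(c(50, 100, 150)), c(2, 1, 2 / 3))
  expect_error(weight_by_trial_count(c(3, 0)), "zero epoch count")
  # grand mean unchanged with equal counts
  set.seed(1)
  erps <- matrix(stats::rnorm(30), 3)
  w <- weight_by_trial_count(c(20, 20, 20))
  expect_equal(colMeans(erps * w), colMeans(erps))
})

test_that("the electrode-extent rule discards narrow clusters", {
  mont <- make_montage(16)
  adj <- channel_adjacency(mont)
  set.seed(43)
  a <- array(stats::rnorm(12 * 16 * 60), c(12, 16, 60))
  b6 <- a; b6[, 1:6, 20:45] <- b6[, 1:6, 20:45] + 2.2
  cl6 <- erp_cluster_test(a, b6, adj, n_permutations = 300, seed = 3,
                          times_s = (0:59) / 250)
  expect_gt(length(cl6), 0)
  best <- cl6[[which.min(vapply(cl6, `[[`, numeric(1), "p"))]]
  expect_lt(best$p, 0.05)
  expect_true(best$onset_s <= 20 / 250 + 0.02)
  # the same effect on only 2 channels is removed by the 4-electrode rule
  b2 <- a; b2[, 1:2, 20:45] <- b2[, 1:2, 20:45] + 2.2
  cl2 <- erp_cluster_test(a, b2, adj, n_permutations = 300, seed = 3)
  wide <- vapply(cl2, function(cl) length(cl$channels) >= 4, logical(1))
  expect_length(cl2[wide], 0)
  expect_gt(attr(cl2, "n_dropped_extent"), 0)
})

test_that("cluster selection keeps the three largest and applies time rules", {
  mk <- function(t_sum, pol, dur, onset) {
    list(polarity = pol, t_sum = t_sum, duration_samples = dur, onset_s = onset)
  }
  cl <- list(mk(50, "positive", 20, 0.1), mk(40, "positive", 20, 0.1),
             mk(30, "positive", 20, 0.1), mk(20, "positive", 20, 0.1),
             mk(10, "positive", 20, 0.1), mk(-60, "negative", 20, 0.1),
             mk(-5, "negative", 4, 0.1), mk(-55, "negative", 20, 0.32))
  out <- select_clusters(cl)
  sums <- vapply(out, `[[`, numeric(1), "t_sum")
  expect_equal(sums, c(-60, 50, 40, 30)) # top-3 per polarity, then filters
  # 8 positive clusters -> at most 3 retained before duration/onset filters
  many <- lapply(seq(80, 10, by = -10), mk, pol = "positive", dur = 20, onset = 0.1)
  expect_length(select_clusters(many), 3)
  expect_length(select_clusters(list(mk(9, "positive", 4, 0.1))), 0)
  expect_length(select_clusters(list(mk(9, "positive", 20, 0.32))), 0)
})

test_that("peak-latency contrast recovers injected shifts and latencies", {
  t <- seq(0, 0.75, by = 1 / 250)
  shape <- function(lat) exp(-((t - lat) / 0.05)^2)
  set.seed(3)
  # occluded-like peaks at 290 ms vs visible-like peaks at 345 ms
  # subject-level latency jitter around injected means of 290 and 345 ms
  mk <- function(lat, n = 12) t(sapply(1:n, function(s) {
    shape(lat + stats::rnorm(1, 0, 0.006))
  }))
  a <- mk(0.290)
  b <- mk(0.345)
  res <- peak_latency_contrast(a, b, t, window = c(0.2, 0.45))
  expect_lt(abs(res$mean_latency_a_s - 0.290), 0.005)
  expect_lt(abs(res$mean_latency_b_s - 0.345), 0.005)
  expect_lt(res$t, 0)
  expect_lt(res$p, 0.01)
  # a +56 ms shift of the same waveforms is recovered at sample resolution
  sh <- t(apply(a, 1, function(x) c(rep(x[1], 14), x[1:(length(x) - 14)])))
  res3 <- peak_latency_contrast(a, sh, t, window = c(0.2, 0.45))
  expect_equal(res3$mean_latency_b_s - res3$mean_latency_a_s, 0.056,
               tolerance = 1 / 250 + 1e-9)
  expect_error(peak_latency_contrast(a, a, t), "zero-variance")
})

test_that("the vincentile-bin matrix has 100 cells of 12-13 samples", {
  t <- seq(-0.5, 187 / 250, by = 1 / 250)
  nt <- length(t)
  set.seed(53)
  mk_cond <- function(n_ep, shift) {
    list(data = array(stats::rnorm(n_ep * 3 * nt, mean = shift), c(n_ep, 3, nt)),
         measure = stats::runif(n_ep, 0.08, 0.3),
         valid = rep(TRUE, n_ep))
  }
  subs <- lapply(1:8, function(s) list(a = mk_cond(40, 0.6), b = mk_cond(40, 0)))
  names(subs) <- paste0("S", 1:8)
  m <- erp_vincentile_matrix(subs, t, cluster_electrodes = 1:3, n_boot = 2000,
                             seed = 3)
  expect_equal(m$n_cells, 100)
  expect_equal(dim(m$t), c(10, 10))
  expect_true(all(m$samples_per_bin %in% c(12, 13)))
  expect_equal(length(m$samples_per_bin), 10)
  # uniformly injected difference: strong effects without a vincentile trend
  expect_gt(sum(m$significant, na.rm = TRUE), 50)
  expect_gt(min(m$d, na.rm = TRUE), 0)
  d_by_vinc <- rowMeans(m$d)
  trend <- stats::cor(seq_len(10), d_by_vinc)
  expect_lt(abs(trend), 0.8)
  # grand mean over cells tracks the mean amplitude over 50-550 ms
  incl <- t >= 0.05 & t < 0.55
  ref <- mean(sapply(subs, function(s) mean(s$a$data[, 1:3, incl])))
  expect_equal(mean(m$values[, 1, , ]), ref, tolerance = 0.05)
})
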