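# Upsampling, RMSE, peak detection/matching, outlier exclusion, sample
# entropy and the interval analysis.

test_that("cubic-spline upsampling reproduces analytic signals", {
  up <- upsample_coordinates(rep(3.5, 60))
  expect_equal(unique(round(up$y, 12)), 3.5)
  expect_equal(length(up$y), ceiling(60 / 60 * 250))
  tt <- (0:119) / 60
  y <- 80 * sin(2 * pi * 2 * tt)
  up2 <- upsample_coordinates(y)
  ref <- 80 * sin(2 * pi * 2 * up2$time_s)
  expect_lt(sqrt(mean((up2$y - ref)^2)), 1e-3 * 80)
  expect_equal(up2$y[1 + 25 * (0:4)], y[1 + 6 * (0:4)])   # coincident instants
  expect_error(upsample_coordinates(1:10, times = c(1:9, 5)), "increasing")
  expect_error(upsample_coordinates(1:3), "at least 4")
})

test_that("epoch error is the RMSE and behaves under affine maps", {
  expect_equal(epoch_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(epoch_error(c(0, 0), c(5, 5)), 5)
  expect_equal(epoch_error(c(0, 0, 0), c(3, 4, 0)), 5 / sqrt(3))
  set.seed(3)
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  expect_equal(epoch_error(a + 7, b + 7), epoch_error(a, b))  # common offset
  expect_equal(epoch_error(3 * a, 3 * b), 3 * epoch_error(a, b))
  expect_error(epoch_error(1:3, 1:4), "mismatch")
})

test_that("peak detection applies the topographic prominence threshold", {
  expect_equal(nrow(detect_peaks(1:100, 0.01, 1080)), 0)
  # triangle wave, amplitude 100 px (prominence 200 at each apex)
  tri <- rep(c(seq(-100, 100, by = 10), seq(90, -90, by = -10)), 5)
  pk1 <- detect_peaks(tri, 0.01, 1080)
  expect_equal(sum(pk1$direction == "max"), 5)
  expect_equal(sum(pk1$direction == "min"), 4)   # troughs between the 5 apexes
  expect_true(all(pk1$prominence[pk1$direction == "max"][2:4] == 200))
  expect_equal(nrow(detect_peaks(tri, 0.25, 1080)), 0)      # 200 < 270
})

test_that("peak matching enforces the latency window, direction and one-to-one use", {
  tp <- data.frame(time_s = c(1.0, 2.0), direction = c("max", "min"))
  pp <- data.frame(time_s = c(1.05, 2.15), direction = c("max", "min"))
  m <- match_pursuit_peaks(tp, pp)
  expect_false(m$valid[1])                                  # +50 ms too early
  expect_true(is.na(m$latency_s[1]))
  expect_equal(m$latency_s[2], 0.15)
  # direction mismatch
  m2 <- match_pursuit_peaks(data.frame(time_s = 1, direction = "max"),
                            data.frame(time_s = 1.15, direction = "min"))
  expect_false(m2$valid)
  # random peak sets vs the brute-force matcher; no pursuit peak reused
  set.seed(17)
  for (rep in 1:25) {
    tpt <- sort(stats::runif(8, 0, 10))
    tpd <- sample(c("max", "min"), 8, TRUE)
    ppt <- sort(stats::runif(12, 0, 10))
    ppd <- sample(c("max", "min"), 12, TRUE)
    m3 <- match_pursuit_peaks(data.frame(time_s = tpt, direction = tpd),
                              data.frame(time_s = ppt, direction = ppd))
    ref <- brute_force_match(tpt, tpd, ppt, ppd)
    expect_equal(m3$pursuit_peak_time_s, ppt[ref])
    used <- m3$pursuit_peak_time_s[m3$valid]
    expect_equal(anyDuplicated(used), 0)
  }
})

test_that("outlier-trial flagging follows the 3-SD rule", {
  expect_equal(exclude_outlier_trials(rep(10, 8))$flagged, integer(0))
  set.seed(61)
  e <- c(stats::rnorm(20, 10, 0.5), 25)        # one gross outlier among 20
  expect_gt(e[21], mean(e) + 4 * stats::sd(e))
  res <- exclude_outlier_trials(e)
  expect_equal(res$flagged, which(e > mean(e) + 3 * stats::sd(e)))
  expect_true(21L %in% res$flagged)
  expect_false(21L %in% res$kept)
  # Monte-Carlo flag rate on Gaussian per-trial maxima ~ upper 3-SD tail mass
  set.seed(29)
  rate <- mean(replicate(400, {
    length(exclude_outlier_trials(stats::rnorm(100))$flagged) / 100
  }))
  expect_lt(rate, 0.01)
})

test_that("sample entropy equals the counting oracle and orders noise above structure", {
  x <- rep(c(1, 2, 3), 4)
  expect_equal(sample_entropy(x, m = 2), sampen_oracle(x, m = 2))
  set.seed(37)
  noise <- stats::rnorm(300)
  expect_equal(sample_entropy(noise), sampen_oracle(noise))
  expect_gt(sample_entropy(noise), sample_entropy(sort(noise)))
  # i.i.d. uniform cross-check at n = 500
  u <- stats::runif(500)
  expect_equal(sample_entropy(u), sampen_oracle(u))
  expect_error(sample_entropy(rep(2, 50)), "zero-variance")
  expect_error(sample_entropy(1:3, m = 2), "too short")
})

test_that("the interval analysis separates structured from noisy error", {
  # both intervals drawn from the same smooth process -> calibrated null
  set.seed(41)
  same <- lapply(1:80, function(i) {
    as.numeric(stats::filter(stats::rnorm(132), rep(1 / 8, 8), sides = 1))[13:132]
  })
  res0 <- entropy_interval_test(same, subjects = rep(1:20, each = 4))
  expect_lt(abs(res0$Z), 2)
  expect_gt(res0$p, 0.05)
  # target-driven (smooth) first interval vs noise-driven remainder
  trials <- list(); subj <- integer(0)
  for (s in 1:8) {
    for (k in 1:6) {
      t1 <- sin(2 * pi * 1.5 * (0:29) / 60 + stats::runif(1, 0, 2 * pi))
      t2 <- stats::rnorm(90, sd = 1)
      trials[[length(trials) + 1L]] <- c(t1, t2) * 40
      subj <- c(subj, s)
    }
  }
  res <- entropy_interval_test(trials, subjects = subj)
  expect_lt(res$median_first, res$median_second)
  expect_lt(res$Z, 0)
  expect_equal(res$effect_r, res$Z / sqrt(res$n_subjects))
  # paired variant runs and agrees in sign
  resp <- entropy_interval_test(trials, subjects = subj, test = "signed_rank")
  expect_lt(resp$Z, 0)
})

test_that("per-epoch metrics carry condition labels and valid flags", {
  traj <- build_trajectory(seed = 51)
  cur <- simulate_cursor(traj, cursor_model_params(smoothing_tau_s = 0,
                                                   motor_noise_sd_px = 0),
                         seed = 1)
  em <- epoch_metrics(traj$y, cur, condition_of = function(t) "all")
  expect_true(all(c("epoch_error_px", "pursuit_latency_s", "valid") %in% names(em)))
  expect_true(all(em$epoch_error_px[!is.na(em$epoch_error_px)] >= 0))
  lat <- em$pursuit_latency_s[em$valid]
  expect_true(all(lat >= 0.08 & lat <= 0.30))
})
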