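# Trajectory formula, random-segment sampling, segment concatenation and
# session plans.

test_that("segment evaluation matches direct evaluation of the formula", {
  cf <- constant_segment_coefficients()
  expect_equal(evaluate_segment(cf, 0), -1)            # 23 - 15 - 9
  expect_equal(evaluate_segment(cf, pi / 2), 26)       # 37 - 26 + 15
  expect_equal(evaluate_segment(segment_coefficients(rep(0, 3), rep(0, 3)),
                                c(-2, 0, 0.7, 10)), rep(0, 4))
  # independent oracle: sum the six terms explicitly at random x
  set.seed(5)
  x <- stats::runif(20, -10, 10)
  manual <- sapply(x, function(xx) {
    sum(cf$a * sin(1:3 * xx)) + sum(cf$b * cos(1:3 * xx))
  })
  expect_equal(evaluate_segment(cf, x), manual)
})

test_that("segment evaluation is linear in the coefficients and rejects bad input", {
  set.seed(8)
  x <- stats::runif(50, 0, 2 * pi)
  c1 <- segment_coefficients(stats::runif(3, -40, 40), stats::runif(3, -40, 40))
  c2 <- segment_coefficients(stats::runif(3, -40, 40), stats::runif(3, -40, 40))
  c12 <- segment_coefficients(c1$a + c2$a, c1$b + c2$b)
  expect_equal(evaluate_segment(c12, x),
               evaluate_segment(c1, x) + evaluate_segment(c2, x))
  expect_error(segment_coefficients(1:2, 1:3), "exactly 3")
  expect_error(evaluate_segment(c1, c(0, NaN)), "finite")
})

test_that("random coefficients are seeded, bounded and keep the segment on screen", {
  expect_identical(sample_random_coefficients(seed = 42),
                   sample_random_coefficients(seed = 42))
  set.seed(123)
  draws <- replicate(10000, unlist(sample_random_coefficients(n_eval = 32)[c("a", "b")]))
  expect_gte(min(draws), -40)
  expect_lte(max(draws), 40)
  # with a small screen the rejection loop must bite: scan accepted draws
  scr <- screen_geometry(height_px = 300)
  x <- seq(0, 2 * pi, length.out = 2048)
  for (s in 1:20) {
    cf <- sample_random_coefficients(seed = s, screen = scr)
    expect_lt(max(abs(evaluate_segment(cf, x))), 300 / 2 - 16)
  }
})

test_that("concatenation bridges gaps with an interpolating cubic", {
  flat <- concatenate_segments(rep(5, 10), rep(5, 10), rep(5, 10))
  expect_equal(unique(flat$y), 5)                      # collinear anchors
  # anchors reproduced exactly across a level change
  seg_a <- seq(0, 1, length.out = 10)
  seg_b <- seq(4, 5, length.out = 10)
  res <- concatenate_segments(seg_a, seg_b, seg_b + 2)
  gap1 <- which(res$segment_labels == "gap")[1] - 1
  expect_equal(res$y[seq_along(seg_a)], seg_a)         # segments unchanged
  expect_equal(res$y[gap1 + 0:1 - 1], seg_a[9:10])
  expect_error(concatenate_segments(numeric(0), 1:5, 1:5), "segment")
})

test_that("a full task-1 trial carries the expected segment label order", {
  traj <- build_trajectory(seed = 11)
  expect_identical(rle(traj$segment_labels)$values,
                   c("start_vector", "random1", "gap", "constant", "gap", "random2"))
  expect_true(all(is.finite(traj$y)))
  # continuity: no frame-to-frame jump far beyond the within-segment maximum
  in_seg <- traj$segment_labels %in% c("random1", "constant", "random2")
  max_seg_jump <- max(abs(diff(traj$y[in_seg])))
  expect_lt(max(abs(diff(traj$y))), 3 * max_seg_jump)
})

test_that("session plans are counterbalanced, reproducible and structured", {
  plan <- build_session_plan(task = 1, seed = 99)
  expect_equal(nrow(plan$trials), 72)
  cells <- table(plan$trials$direction, plan$trials$velocity_level)
  expect_true(all(cells == 12))
  expect_identical(plan$trials, build_session_plan(task = 1, seed = 99)$trials)
  expect_false(identical(plan$trials, build_session_plan(task = 1, seed = 100)$trials))
  expect_equal(plan$break_positions, seq(10, 70, by = 10))
  expect_true(all(plan$trials$fixation_duration_s >= 1 &
                    plan$trials$fixation_duration_s <= 2))
  expect_error(build_session_plan(task = 3), "task")
})

test_that("task-2 occlusion covers 2 s of every 4 s cycle, starting visible", {
  traj <- build_trajectory(seed = 4, task = 2, velocity_level = 2)  # 12 s trial
  occ <- traj$occluded
  t <- traj$time_s
  expect_false(any(occ[t < 2]))                        # starts visible
  expect_true(all(occ[t >= 2 & t < 4]))
  expect_true(all(occ[t >= 6 & t < 8]))
  expect_false(any(occ[t >= 4 & t < 6]))
  expect_equal(mean(occ[t < 12]), 0.5, tolerance = 0.01)
  plan2 <- build_session_plan(task = 2, seed = 1)
  expect_true(all(vapply(plan2$occlusion_intervals, nrow, 1L) > 0))
  expect_equal(plan2$occlusion_intervals[[1]]$start_s[1:2], c(2, 6))
})

test_that("trajectory and session-plan serialization round-trips", {
  traj <- build_trajectory(seed = 21, task = 2)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  d <- utils::read.csv(f)
  expect_identical(names(d),
                   c("frame", "time_s", "x_px", "y_px", "segment_label", "occluded"))
  expect_equal(d$y_px, traj$y)
  plan <- build_session_plan(task = 2, seed = 5)
  pf <- tempfile(fileext = ".json")
  write_session_plan(plan, pf)
  back <- read_session_plan(pf)
  expect_equal(back$trials$trajectory_seed, plan$trials$trajectory_seed)
  expect_equal(back$occlusion_intervals[[3]], plan$occlusion_intervals[[3]])
})
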