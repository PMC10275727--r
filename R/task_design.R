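# Target-trajectory and session-plan generation for the pursuit-tracking tasks.
#
# Each trajectory segment is a sum of three sine and three cosine harmonics,
#   f(x) = sum_{i=1..3} a_i * sin(i * x) + b_i * cos(i * x),
# with x advancing linearly with the target's horizontal position. A trial is a
# short straight start vector followed by three segments (random, constant,
# random) joined across 30-pixel gaps bridged by cubic splines.

#' Segment coefficients
#'
#' Holds the three sine and three cosine amplitudes (pixels) that define one
#' trajectory segment. The constant (repeated) segment uses fixed published
#' coefficients; random segments draw all six uniformly from \[-40, 40\] px.
#'
#' @param a numeric vector of 3 sine amplitudes (pixels).
#' @param b numeric vector of 3 cosine amplitudes (pixels).
#' @return object of class `segment_coefficients`.
#' @export
segment_coefficients <- function(a, b) {
  if (length(a) != 3L || length(b) != 3L) {
    stop("segment coefficients need exactly 3 sine and 3 cosine amplitudes")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("coefficients must be finite")
  structure(list(a = a, b = b), class = "segment_coefficients")
}

#' Coefficients of the constant (repeated) trajectory segment
#' @return `segment_coefficients` with a = (37, -3, 26), b = (23, -15, -9).
#' @export
constant_segment_coefficients <- function() {
  segment_coefficients(c(37, -3, 26), c(23, -15, -9))
}

#' Evaluate a trajectory segment
#'
#' Computes f(x) = sum_i a_i sin(i x) + b_i cos(i x) elementwise.
#'
#' @param coeffs a [segment_coefficients()] object.
#' @param x numeric vector of trajectory parameters (radians; one period is
#'   2 pi).
#' @return vertical positions in pixels, relative to the segment midline.
#' @export
evaluate_segment <- function(coeffs, x) {
  if (!inherits(coeffs, "segment_coefficients")) {
    coeffs <- do.call(segment_coefficients, coeffs)
  }
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("x values must be finite")
  i <- 1:3
  sin_terms <- outer(x, i, function(xx, ii) sin(ii * xx))
  cos_terms <- outer(x, i, function(xx, ii) cos(ii * xx))
  drop(sin_terms %*% coeffs$a + cos_terms %*% coeffs$b)
}

#' Draw random segment coefficients within screen bounds
#'
#' All six coefficients are uniform on \[-40, 40\] px; draws are rejected and
#' resampled until the segment's vertical excursion keeps the target fully on
#' screen (max |f| below half the screen height minus half the target size).
#'
#' @param seed optional integer seed for reproducible draws.
#' @param screen a [screen_geometry()] list.
#' @param target_size_px edge length of the square target (pixels).
#' @param coef_range half-range of the uniform coefficient distribution.
#' @param max_attempts abort after this many rejected draws.
#' @param n_eval grid resolution used to scan the segment for bound violations.
#' @return accepted `segment_coefficients`.
#' @export
sample_random_coefficients <- function(seed = NULL, screen = screen_geometry(),
                                       target_size_px = 32, coef_range = 40,
                                       max_attempts = 10000, n_eval = 512) {
  bound <- screen$height_px / 2 - target_size_px / 2
  x <- seq(0, 2 * pi, length.out = n_eval)
  draw <- function() {
    for (attempt in seq_len(max_attempts)) {
      cf <- segment_coefficients(stats::runif(3, -coef_range, coef_range),
                                 stats::runif(3, -coef_range, coef_range))
      if (max(abs(evaluate_segment(cf, x))) < bound) return(cf)
    }
    stop("no segment within screen bounds after ", max_attempts, " attempts")
  }
  with_seed(seed, draw())
}

# Bridge the gap between two segments with a cubic through the two flanking
# samples on each side. `t_*` are frame times, `y_*` frame values.
bridge_gap <- function(t_left, y_left, t_right, y_right, t_gap) {
  if (length(t_gap) == 0L) return(numeric(0))
  sf <- stats::splinefun(c(t_left, t_right), c(y_left, y_right), method = "fmm")
  sf(t_gap)
}

#' Concatenate three evaluated segments into a trajectory
#'
#' Joins three per-frame segment traces with a horizontal gap (default the
#' 30-pixel gap mapped to frames via `px_per_frame`) bridged by a cubic spline
#' through the two flanking samples on each side, so the result is continuous.
#'
#' @param seg1,seg2,seg3 numeric vectors of per-frame vertical positions.
#' @param gap_px horizontal width of the gap between segments (pixels).
#' @param px_per_frame horizontal advance of the target per frame (pixels).
#' @param labels labels for the three segments.
#' @return list with `y` (pixels) and `segment_labels` (one per frame; bridged
#'   frames are tagged `"gap"`).
#' @export
concatenate_segments <- function(seg1, seg2, seg3, gap_px = 30, px_per_frame = 8/3,
                                 labels = c("random1", "constant", "random2")) {
  segs <- list(seg1, seg2, seg3)
  if (any(vapply(segs, length, 1L) < 2L)) stop("empty or single-frame segment")
  n_gap <- max(1L, round(gap_px / px_per_frame))
  y <- segs[[1]]
  lab <- rep(labels[1], length(seg1))
  t_now <- length(seg1)
  for (k in 2:3) {
    nxt <- segs[[k]]
    t_gap <- t_now + seq_len(n_gap)
    t_next <- t_now + n_gap + seq_along(nxt)
    bridge <- bridge_gap(t_left = c(t_now - 1, t_now), y_left = y[(length(y) - 1):length(y)],
                         t_right = t_next[1:2], y_right = nxt[1:2], t_gap = t_gap)
    y <- c(y, bridge, nxt)
    lab <- c(lab, rep("gap", n_gap), rep(labels[k], length(nxt)))
    t_now <- t_next[length(t_next)]
  }
  list(y = y, segment_labels = lab)
}

#' Build one trial's target trajectory
#'
#' Assembles the start vector (500 ms at screen-centre height, its tail ramped
#' smoothly onto the first segment) and the three spline-joined segments, maps
#' frames to horizontal positions for the chosen direction and velocity, and
#' attaches the occlusion mask for the occlusion task.
#'
#' @param direction `"left"` or `"right"`.
#' @param velocity_level 1 (slow), 2, or 3 (fast); levels map to trial
#'   durations of 13.5, 12 and 10.5 s so the mean trial lasts 12 s.
#' @param seed seed for the two random segments.
#' @param task 1 (plain tracking) or 2 (cursor occluded 2 s of every 4 s,
#'   starting visible).
#' @param config a [study_config()] list (screen, frame rate, gap, start
#'   vector, velocity durations).
#' @return object of class `trajectory`: per-frame `y` (pixels), `time_s`,
#'   `x_px`, `segment_labels`, `occluded`, plus metadata.
#' @export
build_trajectory <- function(direction = c("right", "left"), velocity_level = 2,
                             seed = NULL, task = 1, config = study_config()) {
  direction <- match.arg(direction)
  stopifnot(velocity_level %in% 1:3, task %in% 1:2)
  scr <- screen_geometry(config$screen_width_px, config$screen_height_px)
  fr <- config$behavior_rate_hz
  dur <- config$velocity_durations_s[velocity_level]
  n_total <- round(dur * fr)
  ppf <- scr$width_px / n_total
  n_start <- round(config$start_vector_s * fr)
  n_gap <- max(1L, round(config$gap_px / ppf))
  n_seg <- floor((n_total - n_start - 2L * n_gap) / 3)

  x_param <- seq(0, 2 * pi, length.out = n_seg)
  cf1 <- sample_random_coefficients(seed = if (is.null(seed)) NULL else derive_seed(seed, 1),
                                    screen = scr, target_size_px = config$target_size_px)
  cf3 <- sample_random_coefficients(seed = if (is.null(seed)) NULL else derive_seed(seed, 2),
                                    screen = scr, target_size_px = config$target_size_px)
  seg1 <- evaluate_segment(cf1, x_param)
  seg2 <- evaluate_segment(constant_segment_coefficients(), x_param)
  seg3 <- evaluate_segment(cf3, x_param)

  path <- concatenate_segments(seg1, seg2, seg3, gap_px = config$gap_px, px_per_frame = ppf)

  # Start vector: constant centre height; final frames ease cubically onto the
  # first segment sample so the full trace stays continuous.
  start_y <- rep(0, n_start)
  n_ramp <- min(n_start, round(0.25 * fr))
  if (n_ramp > 1L) {
    u <- seq(0, 1, length.out = n_ramp)
    start_y[(n_start - n_ramp + 1L):n_start] <- path$y[1] * (3 * u^2 - 2 * u^3)
  }

  y <- c(start_y, path$y) + scr$center_y_px
  labels <- c(rep("start_vector", n_start), path$segment_labels)
  n <- length(y)
  time_s <- (seq_len(n) - 1) / fr
  x_px <- (seq_len(n) - 1) * ppf
  if (direction == "left") x_px <- scr$width_px - x_px

  occluded <- rep(FALSE, n)
  if (task == 2) {
    cyc <- config$occlusion_visible_s + config$occlusion_occluded_s
    occluded <- (time_s %% cyc) >= config$occlusion_visible_s
  }

  structure(list(y = y, time_s = time_s, x_px = x_px, segment_labels = labels,
                 occluded = occluded, frame_rate = fr, direction = direction,
                 velocity_level = velocity_level, task = task,
                 coefficients = list(random1 = cf1,
                                     constant = constant_segment_coefficients(),
                                     random2 = cf3),
                 px_per_frame = ppf),
            class = "trajectory")
}

#' Occlusion intervals of a trial
#'
#' @param duration_s trial duration in seconds.
#' @param visible_s,occluded_s lengths of the alternating visible and occluded
#'   periods; the trial starts visible.
#' @return data.frame with `start_s`, `end_s` per occluded interval.
#' @export
occlusion_intervals <- function(duration_s, visible_s = 2, occluded_s = 2) {
  cyc <- visible_s + occluded_s
  starts <- seq(visible_s, duration_s, by = cyc)
  starts <- starts[starts < duration_s]
  data.frame(start_s = starts, end_s = pmin(starts + occluded_s, duration_s))
}

#' Build a counterbalanced session plan
#'
#' 2 directions x 3 velocity levels, each combination repeated
#' `config$n_reps_per_cell` times (default 12, i.e. 72 trials), in seeded
#' shuffled order. Inter-trial fixation durations are uniform on \[1, 2\] s
#' (mean 1.5 s); a 30-s break follows every 10 trials. Task-2 plans carry the
#' per-trial occlusion intervals.
#'
#' @param task 1 or 2.
#' @param seed integer seed; plans are exactly reproducible from (task, seed).
#' @param config a [study_config()] list.
#' @return object of class `session_plan` with `trials` (data.frame: trial,
#'   direction, velocity_level, trajectory_seed, duration_s,
#'   fixation_duration_s), `break_positions`, `occlusion_intervals`.
#' @export
build_session_plan <- function(task = 1, seed = 1, config = study_config()) {
  if (!task %in% 1:2) stop("task must be 1 or 2")
  cells <- expand.grid(direction = c("left", "right"), velocity_level = 1:3,
                       rep = seq_len(config$n_reps_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(cells)
  plan <- with_seed(seed, {
    ord <- sample.int(n)
    fix <- stats::runif(n, config$fixation_min_s, config$fixation_max_s)
    tseed <- floor(stats::runif(n, 0, 2^31 - 1))
    list(ord = ord, fix = fix, tseed = tseed)
  })
  trials <- cells[plan$ord, c("direction", "velocity_level")]
  trials$trial <- seq_len(n)
  trials$trajectory_seed <- plan$tseed
  trials$duration_s <- config$velocity_durations_s[trials$velocity_level]
  trials$fixation_duration_s <- plan$fix
  rownames(trials) <- NULL
  trials <- trials[, c("trial", "direction", "velocity_level", "trajectory_seed",
                       "duration_s", "fixation_duration_s")]
  occl <- if (task == 2) {
    lapply(trials$duration_s, occlusion_intervals,
           visible_s = config$occlusion_visible_s,
           occluded_s = config$occlusion_occluded_s)
  } else {
    rep(list(data.frame(start_s = numeric(0), end_s = numeric(0))), n)
  }
  structure(list(task = task, seed = seed, trials = trials,
                 break_positions = seq(config$break_every, n - 1, by = config$break_every),
                 break_duration_s = config$break_duration_s,
                 occlusion_intervals = occl),
            class = "session_plan")
}

#' Convert a trajectory to its on-disk data.frame form
#'
#' Column names are part of the file contract: `frame`, `time_s`, `x_px`,
#' `y_px`, `segment_label`, `occluded`.
#' @param traj a `trajectory`.
#' @return data.frame in the documented CSV dialect.
#' @export
trajectory_to_df <- function(traj) {
  data.frame(frame = seq_along(traj$y), time_s = traj$time_s, x_px = traj$x_px,
             y_px = traj$y, segment_label = traj$segment_labels,
             occluded = traj$occluded)
}

#' Write a trajectory CSV
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(trajectory_to_df(traj), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a session plan (JSON)
#' @param plan a `session_plan`.
#' @param path file path.
#' @export
write_session_plan <- function(plan, path) {
  obj <- list(task = plan$task, seed = plan$seed, trials = plan$trials,
              break_positions = plan$break_positions,
              break_duration_s = plan$break_duration_s,
              occlusion_intervals = plan$occlusion_intervals)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_session_plan
#' @export
read_session_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  occl <- obj$occlusion_intervals
  if (is.data.frame(occl)) occl <- list(occl)
  occl <- lapply(occl, function(d) {
    if (length(d) == 0L || is.null(d$start_s)) {
      data.frame(start_s = numeric(0), end_s = numeric(0))
    } else as.data.frame(d)
  })
  structure(list(task = obj$task, seed = obj$seed, trials = as.data.frame(obj$trials),
                 break_positions = obj$break_positions,
                 break_duration_s = obj$break_duration_s,
                 occlusion_intervals = occl),
            class = "session_plan")
}
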