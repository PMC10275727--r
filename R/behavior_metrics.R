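# Tracking-performance measures: cubic-spline upsampling, epoch RMSE,
# prominence-based peak detection, trajectory-to-pursuit peak matching,
# outlier-trial exclusion, and the sample-entropy interval analysis.

#' Upsample a coordinate trace with cubic splines
#'
#' Interpolates a 60 Hz behavioral trace onto the EEG sampling grid (250 Hz by
#' default) with a cubic spline; the interpolant passes through every original
#' sample.
#'
#' @param y per-frame positions.
#' @param from_hz,to_hz input and output sampling rates.
#' @param times optional explicit timestamps (must be strictly increasing).
#' @return list with `y` and `time_s` on the output grid; the output length is
#'   `ceiling(duration * to_hz)` where duration is `length(y) / from_hz`.
#' @export
upsample_coordinates <- function(y, from_hz = 60, to_hz = 250, times = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples for cubic-spline upsampling")
  if (is.null(times)) times <- (seq_len(n) - 1) / from_hz
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing")
  n_out <- ceiling(n / from_hz * to_hz)
  t_out <- (seq_len(n_out) - 1) / to_hz
  sf <- stats::splinefun(times, y, method = "fmm")
  list(y = sf(t_out), time_s = t_out)
}

#' Epoch tracking error (RMSE)
#'
#' Root mean squared vertical distance between target and cursor.
#' @param target_y,cursor_y equal-length traces (pixels).
#' @return RMSE in pixels.
#' @export
epoch_error <- function(target_y, cursor_y) {
  if (length(target_y) != length(cursor_y)) stop("trace length mismatch")
  if (length(target_y) < 1L) stop("empty traces")
  sqrt(mean((target_y - cursor_y)^2))
}

# Topographic prominence of the local maxima at positions `peaks` of `x`:
# for each peak, walk out to the nearest higher sample (or the series edge) on
# both sides, take the minimum on each side, and subtract the higher of the two
# minima from the peak height.
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    left_min <- h
    while (i > 1L) {
      i <- i - 1L
      if (x[i] > h) break
      if (x[i] < left_min) left_min <- x[i]
    }
    i <- p
    right_min <- h
    while (i < n) {
      i <- i + 1L
      if (x[i] > h) break
      if (x[i] < right_min) right_min <- x[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

# Indices of strict local maxima; flat plateaus contribute their centre sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  idx <- integer(0)
  i <- 1L
  while (i < n) {
    if (d[i] > 0) {
      j <- i + 1L
      while (j < n && d[j] == 0) j <- j + 1L
      if (j <= n - 1L && d[j] < 0) idx <- c(idx, as.integer(floor((i + 1L + j) / 2)))
      i <- j
    } else i <- i + 1L
  }
  idx
}

#' Detect trajectory / pursuit peaks by topographic prominence
#'
#' Local maxima and minima whose prominence reaches `prominence_fraction` of
#' the screen size (the vertical extent). Minima are found by negating the
#' series. The target trace uses a 1% threshold, the noisier pursuit trace 5%.
#'
#' @param series numeric trace (pixels).
#' @param prominence_fraction fraction of `screen_size_px` a peak must stand
#'   out from its surroundings.
#' @param screen_size_px reference size (default 1080, the screen height).
#' @param times optional timestamps; defaults to sample index / `rate_hz`.
#' @param rate_hz sampling rate used when `times` is missing.
#' @return data.frame: `index`, `time_s`, `direction` ("max"/"min"), `value`,
#'   `prominence`; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(series, prominence_fraction, screen_size_px = 1080,
                         times = NULL, rate_hz = 250) {
  if (prominence_fraction <= 0) stop("prominence_fraction must be positive")
  series <- as.numeric(series)
  if (is.null(times)) times <- (seq_along(series) - 1) / rate_hz
  thr <- prominence_fraction * screen_size_px
  out <- list()
  for (dir in c("max", "min")) {
    x <- if (dir == "max") series else -series
    idx <- local_maxima(x)
    if (length(idx)) {
      prom <- peak_prominence(x, idx)
      keep <- prom >= thr
      if (any(keep)) {
        out[[dir]] <- data.frame(index = idx[keep], time_s = times[idx[keep]],
                                 direction = dir, value = series[idx[keep]],
                                 prominence = prom[keep])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(index = integer(0), time_s = numeric(0),
                      direction = character(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$index), ]
  rownames(res) <- NULL
  res
}

#' Match trajectory peaks to following pursuit peaks
#'
#' A pursuit peak is a valid match for a trajectory peak when it follows it by
#' 80-300 ms and has the same direction (both maxima or both minima). Matching
#' is one-to-one and greedy in time order: each trajectory peak takes the
#' earliest unused same-direction in-window pursuit peak.
#'
#' @param traj_peaks,pursuit_peaks data.frames from [detect_peaks()],
#'   time-sorted.
#' @param window valid latency window in seconds.
#' @return data.frame: `trajectory_peak_time_s`, `pursuit_peak_time_s`,
#'   `latency_s`, `direction`, `valid`; invalid matches carry NA latency.
#' @export
match_pursuit_peaks <- function(traj_peaks, pursuit_peaks, window = c(0.08, 0.30)) {
  nt <- nrow(traj_peaks)
  res <- data.frame(trajectory_peak_time_s = traj_peaks$time_s,
                    pursuit_peak_time_s = NA_real_, latency_s = NA_real_,
                    direction = traj_peaks$direction, valid = FALSE)
  if (nt == 0L) return(res)
  used <- rep(FALSE, nrow(pursuit_peaks))
  for (i in seq_len(nt)) {
    lat <- pursuit_peaks$time_s - traj_peaks$time_s[i]
    cand <- which(!used & pursuit_peaks$direction == traj_peaks$direction[i] &
                    lat >= window[1] & lat <= window[2])
    if (length(cand)) {
      j <- cand[which.min(pursuit_peaks$time_s[cand])]
      used[j] <- TRUE
      res$pursuit_peak_time_s[i] <- pursuit_peaks$time_s[j]
      res$latency_s[i] <- lat[j]
      res$valid[i] <- TRUE
    }
  }
  res
}

#' Flag outlier trials by maximum tracking error
#'
#' Flags trials whose maximum absolute tracking error exceeds the within-subject
#' mean by more than `n_sd` standard deviations of the per-trial maxima
#' (automating the study's manual-inspection step). When the SD is zero (all
#' trials identical) nothing is flagged.
#'
#' @param max_errors per-trial maximum absolute tracking error (pixels).
#' @param n_sd flagging threshold in standard deviations.
#' @return list with `kept` and `flagged` (indices into `max_errors`).
#' @export
exclude_outlier_trials <- function(max_errors, n_sd = 3) {
  max_errors <- as.numeric(max_errors)
  if (length(max_errors) < 2L) stop("need at least 2 trials")
  s <- stats::sd(max_errors)
  flagged <- if (is.na(s) || s == 0) integer(0) else {
    which(max_errors > mean(max_errors) + n_sd * s)
  }
  list(kept = setdiff(seq_along(max_errors), flagged), flagged = flagged)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of length-m templates and A
#' pairs of length-(m+1) templates whose Chebyshev distance is at most r;
#' self-matches are excluded. The similarity criterion defaults to 0.2 times
#' the series standard deviation.
#'
#' @param x numeric series (length > m + 1).
#' @param m template length (default 2).
#' @param r similarity criterion in the units of `x`; default `0.2 * sd(x)`.
#' @return sample entropy (dimensionless; `Inf` when no (m+1)-template pair
#'   matches, `NaN` when no m-template pair matches).
#' @export
sample_entropy <- function(x, m = 2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1L) stop("series too short for sample entropy with m = ", m)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance series: sample entropy undefined")
  if (is.null(r)) r <- 0.2 * s
  n_templates <- n - m           # templates of length m+1 live at 1..n-m
  b_count <- 0
  a_count <- 0
  for (d in seq_len(n_templates - 1L)) {
    i_max <- n_templates - d
    idx <- seq_len(i_max)
    cheb <- abs(x[idx] - x[idx + d])
    for (k in seq_len(m - 1L)) {
      cheb <- pmax(cheb, abs(x[idx + k] - x[idx + d + k]))
    }
    match_m <- cheb <= r
    b_count <- b_count + sum(match_m)
    if (any(match_m)) {
      cheb1 <- pmax(cheb, abs(x[idx + m] - x[idx + d + m]))
      a_count <- a_count + sum(match_m & cheb1 <= r)
    }
  }
  -log(a_count / b_count)
}

# Wilcoxon rank-sum Z via the normal approximation with tie and continuity
# correction (the large-sample statistic behind stats::wilcox.test).
rank_sum_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  rks <- rank(c(a, b))
  w <- sum(rks[seq_len(n1)]) - n1 * (n1 + 1) / 2      # Mann-Whitney U of group a
  mu <- n1 * n2 / 2
  ties <- table(rks)
  sigma2 <- (n1 * n2 / 12) * ((n1 + n2 + 1) -
                                sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  correction <- sign(w - mu) * 0.5
  z <- (w - mu - correction) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sample-entropy interval analysis of the tracking error
#'
#' Splits each trial's signed tracking error into the initial interval
#' (0-500 ms) and the following interval (500-2000 ms), z-transforms each
#' interval individually, computes sample entropy per interval, aggregates per
#' subject, and compares the two intervals across subjects with a Wilcoxon
#' rank-sum test. The effect size follows the r = Z / sqrt(N) convention with
#' N the number of subjects.
#'
#' @param errors list of per-trial signed error traces (target minus cursor).
#' @param subjects subject id per trial (same length as `errors`).
#' @param rate_hz sampling rate of the error traces (60 Hz behavioral frames).
#' @param split_at_s boundary between the two intervals (default 0.5 s).
#' @param horizon_s end of the second interval (default 2 s).
#' @param m,r_factor sample-entropy parameters (template length; similarity
#'   criterion as a fraction of the SD, applied after z-scoring).
#' @param aggregate per-subject reducer over trials, `"median"` (default) or
#'   `"mean"`.
#' @param test `"rank_sum"` (unpaired, as reported) or `"signed_rank"` (paired
#'   variant).
#' @return list of class `entropy_result`: `per_subject_first`,
#'   `per_subject_second`, medians, `Z`, `p`, `effect_r`, `n_skipped`.
#' @export
entropy_interval_test <- function(errors, subjects, rate_hz = 60,
                                  split_at_s = 0.5, horizon_s = 2.0,
                                  m = 2, r_factor = 0.2,
                                  aggregate = c("median", "mean"),
                                  test = c("rank_sum", "signed_rank")) {
  aggregate <- match.arg(aggregate)
  test <- match.arg(test)
  stopifnot(length(errors) == length(subjects))
  n_split <- round(split_at_s * rate_hz)
  n_hor <- round(horizon_s * rate_hz)
  reducer <- if (aggregate == "median") stats::median else mean

  ent1 <- ent2 <- rep(NA_real_, length(errors))
  n_skipped <- 0L
  for (i in seq_along(errors)) {
    e <- as.numeric(errors[[i]])
    if (length(e) < n_hor) { n_skipped <- n_skipped + 1L; next }
    seg1 <- e[seq_len(n_split)]
    seg2 <- e[(n_split + 1L):n_hor]
    ok <- tryCatch({
      z1 <- (seg1 - mean(seg1)) / stats::sd(seg1)
      z2 <- (seg2 - mean(seg2)) / stats::sd(seg2)
      ent1[i] <- sample_entropy(z1, m = m, r = r_factor)
      ent2[i] <- sample_entropy(z2, m = m, r = r_factor)
      TRUE
    }, error = function(err) FALSE)
    if (!ok) n_skipped <- n_skipped + 1L
  }

  agg <- function(v) {
    out <- tapply(v, subjects, function(x) {
      x <- x[is.finite(x)]
      if (!length(x)) NA_real_ else reducer(x)
    })
    out[!is.na(out)]
  }
  per1 <- agg(ent1)
  per2 <- agg(ent2)
  common <- intersect(names(per1), names(per2))
  per1 <- per1[common]; per2 <- per2[common]
  n_sub <- length(common)
  if (n_sub < 2L) stop("need entropy values for at least 2 subjects")

  if (test == "rank_sum") {
    zt <- rank_sum_z(per1, per2)
  } else {
    d <- (per1 - per2)[per1 != per2]
    nn <- length(d)
    if (nn < 2L) stop("signed-rank test needs at least 2 non-tied pairs")
    rk <- rank(abs(d))
    v <- sum(rk[d > 0])
    mu <- nn * (nn + 1) / 4
    sigma2 <- nn * (nn + 1) * (2 * nn + 1) / 24
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    zt <- list(z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  structure(list(per_subject_first = per1, per_subject_second = per2,
                 median_first = stats::median(per1),
                 median_second = stats::median(per2),
                 Z = zt$z, p = zt$p, effect_r = zt$z / sqrt(n_sub),
                 n_subjects = n_sub, n_skipped = n_skipped,
                 aggregate = aggregate, test = test),
            class = "entropy_result")
}

#' Per-epoch behavioral metrics around trajectory peaks
#'
#' The analysis unit ("epoch") is a window around each detected target
#' direction change. For each epoch this computes the RMSE between target and
#' cursor over the window and the pursuit latency from one-to-one peak
#' matching, after upsampling both traces to the EEG rate.
#'
#' @param target_y,cursor_y per-frame traces at `from_hz`.
#' @param from_hz behavioral frame rate (60 Hz).
#' @param to_hz analysis rate (250 Hz).
#' @param window epoch window around each trajectory peak, seconds.
#' @param config a [study_config()] (prominence fractions, latency window,
#'   screen size).
#' @param condition_of optional function(time_s) returning a condition label
#'   per peak time (e.g. segment or occlusion state).
#' @return data.frame: one row per trajectory peak with `peak_time_s`,
#'   `direction`, `condition`, `epoch_error_px`, `pursuit_latency_s`, `valid`.
#' @export
epoch_metrics <- function(target_y, cursor_y, from_hz = 60, to_hz = 250,
                          window = c(-0.5, 0.75), config = study_config(),
                          condition_of = NULL) {
  up_t <- upsample_coordinates(target_y, from_hz, to_hz)
  up_c <- upsample_coordinates(cursor_y, from_hz, to_hz)
  scr <- config$screen_height_px
  tp <- detect_peaks(up_t$y, config$prominence_fraction_target, scr,
                     times = up_t$time_s)
  pp <- detect_peaks(up_c$y, config$prominence_fraction_pursuit, scr,
                     times = up_c$time_s)
  matches <- match_pursuit_peaks(tp, pp, window = config$latency_window_s)
  n <- nrow(matches)
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t0 <- matches$trajectory_peak_time_s[i]
    sel <- up_t$time_s >= t0 + window[1] & up_t$time_s <= t0 + window[2]
    if (any(sel)) err[i] <- epoch_error(up_t$y[sel], up_c$y[sel])
  }
  cond <- if (is.null(condition_of)) NA_character_ else {
    vapply(matches$trajectory_peak_time_s, condition_of, character(1))
  }
  data.frame(peak_time_s = matches$trajectory_peak_time_s,
             direction = matches$direction, condition = cond,
             epoch_error_px = err,
             pursuit_latency_s = matches$latency_s, valid = matches$valid)
}
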