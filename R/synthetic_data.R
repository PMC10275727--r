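# Synthetic cursor behavior and EEG with known ground truth, so every
# downstream stage is testable without the deposited recordings.

#' Deterministic 60-channel montage
#'
#' Equidistant positions on the upper part of a unit sphere (golden-angle
#' spiral over a spherical cap), emulating an equidistant 10%-system cap.
#'
#' @param n_channels number of electrodes (default 60).
#' @param z_min lower cap boundary (default -0.2, slightly below the equator).
#' @return data.frame: `channel` (E01...), `x`, `y`, `z` on the unit sphere.
#' @export
make_montage <- function(n_channels = 60, z_min = -0.2) {
  i <- seq_len(n_channels)
  z <- 1 - (i - 0.5) / n_channels * (1 - z_min)
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  data.frame(channel = sprintf("E%02d", i),
             x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Cursor-controller parameters
#'
#' First-order tracking model: the cursor rests at screen centre for an
#' initial dead time (participants typically do not move the joystick during
#' the first ~500 ms), then follows a lag-shifted, exponentially smoothed copy
#' of the target with additive Gaussian motor noise; the noise is scaled up
#' while the cursor is occluded.
#'
#' @param dead_time_s initial no-movement period (s).
#' @param lag_s tracking delay, within \[0, 0.5\] s.
#' @param smoothing_tau_s low-pass time constant (s); 0 disables smoothing.
#' @param motor_noise_sd_px per-frame Gaussian noise SD (pixels).
#' @param occlusion_noise_gain noise multiplier while occluded.
#' @return list of class `cursor_model_params`.
#' @export
cursor_model_params <- function(dead_time_s = 0.5, lag_s = 0.15,
                                smoothing_tau_s = 0.05, motor_noise_sd_px = 8,
                                occlusion_noise_gain = 1.5) {
  vals <- c(dead_time_s, lag_s, smoothing_tau_s, motor_noise_sd_px,
            occlusion_noise_gain)
  if (any(vals < 0)) stop("cursor parameters must be non-negative")
  if (lag_s > 0.5) stop("lag_s must lie within [0, 0.5] s")
  structure(list(dead_time_s = dead_time_s, lag_s = lag_s,
                 smoothing_tau_s = smoothing_tau_s,
                 motor_noise_sd_px = motor_noise_sd_px,
                 occlusion_noise_gain = occlusion_noise_gain),
            class = "cursor_model_params")
}

#' Simulate a cursor trace for one trial
#'
#' @param traj a `trajectory` from [build_trajectory()] (60 Hz).
#' @param params a [cursor_model_params()].
#' @param seed optional seed.
#' @param center_y_px resting cursor height (defaults to the trajectory's
#'   start-vector height).
#' @return numeric per-frame cursor y positions (pixels).
#' @export
simulate_cursor <- function(traj, params = cursor_model_params(), seed = NULL,
                            center_y_px = NULL) {
  fr <- traj$frame_rate
  y <- traj$y
  n <- length(y)
  center <- center_y_px %||% y[1]
  dt <- 1 / fr
  lag_frames <- round(params$lag_s * fr)
  target_lagged <- c(rep(y[1], lag_frames), y)[seq_len(n)]
  alpha <- if (params$smoothing_tau_s < dt / 2) 1 else 1 - exp(-dt / params$smoothing_tau_s)
  dead_frames <- round(params$dead_time_s * fr)
  cursor <- numeric(n)
  prev <- center
  for (t in seq_len(n)) {
    if (t <= dead_frames) {
      cursor[t] <- center
    } else {
      cursor[t] <- prev + alpha * (target_lagged[t] - prev)
    }
    prev <- cursor[t]
  }
  if (params$motor_noise_sd_px > 0) {
    gain <- ifelse(traj$occluded, params$occlusion_noise_gain, 1)
    noise <- with_seed(seed, stats::rnorm(n, 0, params$motor_noise_sd_px))
    active <- seq_len(n) > dead_frames
    cursor[active] <- cursor[active] + (noise * gain)[active]
  }
  cursor
}

#' EEG effect specification
#'
#' Declares the ground-truth structure injected into synthetic EEG: per-band,
#' per-condition oscillation amplitudes, a peak-locked ERP template with
#' per-condition scaling, the 1/f noise exponent, and the affected channels.
#'
#' @param band_effects named list over bands (`theta`, `alpha`, `beta`), each
#'   a named numeric vector of oscillation amplitudes (uV) per condition.
#' @param erp_template list with `times_s` and `amplitude_uv` (zero outside
#'   its support), or NULL for no evoked response.
#' @param erp_condition_scale named scaling of the template per condition.
#' @param noise_exponent 1/f spectral slope (default 1).
#' @param noise_sd_uv broadband noise SD per channel (uV).
#' @param channels_affected channel indices carrying the oscillation and ERP
#'   effects.
#' @return list of class `eeg_effect_spec`.
#' @export
eeg_effect_spec <- function(band_effects = list(), erp_template = NULL,
                            erp_condition_scale = NULL, noise_exponent = 1,
                            noise_sd_uv = 10, channels_affected = NULL) {
  stopifnot(noise_exponent >= 0, noise_sd_uv >= 0)
  if (length(band_effects) &&
      !all(names(band_effects) %in% c("theta", "alpha", "beta"))) {
    stop("band_effects must be named theta/alpha/beta")
  }
  structure(list(band_effects = band_effects, erp_template = erp_template,
                 erp_condition_scale = erp_condition_scale,
                 noise_exponent = noise_exponent, noise_sd_uv = noise_sd_uv,
                 channels_affected = channels_affected),
            class = "eeg_effect_spec")
}

# 1/f^exponent noise of length n, unit SD, via spectral shaping of white noise.
one_over_f_noise <- function(n, exponent, sfreq) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1e-12, seq_len(n - 1)) * sfreq / n
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]   # mirror for negative freqs
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

band_center <- c(theta = 5.5, alpha = 10, beta = 20)

#' Simulate continuous multichannel EEG with injected effects
#'
#' Signal per channel = 1/f noise + band-limited oscillations whose amplitude
#' is scaled by condition inside each condition window + an ERP template added
#' at each direction-change event; sampled at 250 Hz.
#'
#' @param events data.frame: `time_s`, `condition` — one row per direction
#'   change.
#' @param montage data.frame from [make_montage()].
#' @param spec an [eeg_effect_spec()].
#' @param duration_s recording length (s).
#' @param sfreq sampling rate (250 Hz).
#' @param condition_windows data.frame `onset_s`, `duration_s`, `condition`
#'   defining where each condition's band amplitudes apply; defaults to the
#'   whole recording for every condition named in `spec`.
#' @param t0 time of the first sample (default 0).
#' @param seed optional seed.
#' @return list: `data` (channels x samples, uV), `sfreq`, `t0`, `montage`,
#'   `events`, `ground_truth` (the injected effects).
#' @export
simulate_eeg <- function(events, montage, spec = eeg_effect_spec(),
                         duration_s, sfreq = 250, condition_windows = NULL,
                         t0 = 0, seed = NULL) {
  n <- round(duration_s * sfreq)
  nch <- nrow(montage)
  tvec <- t0 + (seq_len(n) - 1) / sfreq
  if (nrow(events) && (any(events$time_s < t0) ||
                       any(events$time_s > t0 + duration_s))) {
    stop("events outside the recording span")
  }
  affected <- spec$channels_affected %||% seq_len(nch)
  if (any(affected > nch)) stop("montage/channel mismatch in channels_affected")
  conds <- unique(c(names(unlist(lapply(spec$band_effects, names))) %||% character(0),
                    unlist(lapply(spec$band_effects, names)),
                    as.character(events$condition)))
  if (is.null(condition_windows)) {
    condition_windows <- if (length(conds)) {
      data.frame(onset_s = t0, duration_s = duration_s, condition = unique(conds))
    } else {
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 condition = character(0))
    }
  }
  data <- with_seed(seed, {
    out <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      out[ch, ] <- spec$noise_sd_uv * one_over_f_noise(n, spec$noise_exponent, sfreq)
    }
    for (band in names(spec$band_effects)) {
      fc <- band_center[[band]]
      for (ch in affected) {
        phase <- stats::runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * fc * (tvec - t0) + phase)
        amp <- numeric(n)
        for (w in seq_len(nrow(condition_windows))) {
          cnd <- condition_windows$condition[w]
          a <- spec$band_effects[[band]][[cnd]] %||% 0
          if (is.na(a) || a == 0) next
          sel <- tvec >= condition_windows$onset_s[w] &
            tvec < condition_windows$onset_s[w] + condition_windows$duration_s[w]
          amp[sel] <- a
        }
        out[ch, ] <- out[ch, ] + amp * carrier
      }
    }
    if (!is.null(spec$erp_template) && nrow(events)) {
      tmpl_t <- spec$erp_template$times_s
      tmpl_a <- spec$erp_template$amplitude_uv
      offs <- round(tmpl_t * sfreq)
      for (e in seq_len(nrow(events))) {
        scale <- if (is.null(spec$erp_condition_scale)) 1 else {
          spec$erp_condition_scale[[as.character(events$condition[e])]] %||% 1
        }
        c0 <- round((events$time_s[e] - t0) * sfreq) + 1L
        idx <- c0 + offs
        keep <- idx >= 1L & idx <= n
        for (ch in affected) {
          out[ch, idx[keep]] <- out[ch, idx[keep]] + scale * tmpl_a[keep]
        }
      }
    }
    out
  })
  ground_truth <- list(band_effects = spec$band_effects,
                       erp_condition_scale = spec$erp_condition_scale,
                       noise_exponent = spec$noise_exponent,
                       channels_affected = affected,
                       condition_windows = condition_windows)
  list(data = data, sfreq = sfreq, t0 = t0, montage = montage,
       events = events, ground_truth = ground_truth)
}

#' Generate a full synthetic study
#'
#' Builds, per subject, a counterbalanced session plan, target trajectories,
#' simulated cursor traces, per-epoch behavioral metrics, and (optionally)
#' trial EEG with injected effects — plus a ground-truth manifest listing
#' every injected parameter. The defaults mirror the study design: 30
#' subjects, 72 trials (2 directions x 3 velocities x 12 repetitions).
#'
#' @param n_subjects number of subjects (>= 2; default 30).
#' @param task 1 or 2.
#' @param cursor_params a [cursor_model_params()] shared by all subjects, or a
#'   list of one per subject.
#' @param eeg_spec an [eeg_effect_spec()] (used when `include_eeg`).
#' @param seed study seed; the same seed reproduces the dataset exactly.
#' @param config a [study_config()].
#' @param n_trials trials per subject (NULL = the full 72-trial plan).
#' @param include_eeg simulate EEG for the first `eeg_trials_per_subject`
#'   trials of each subject.
#' @param eeg_trials_per_subject EEG trial count per subject (memory guard;
#'   NULL = all trials).
#' @param n_channels montage size for simulated EEG.
#' @return list of class `synthetic_study`: `subjects` (list with `plan`,
#'   `trials` — each trial has `trajectory`, `cursor_y` — and `eeg` per EEG
#'   trial), `metrics` (per-epoch data.frame across subjects), `ground_truth`,
#'   `config`.
#' @export
make_study <- function(n_subjects = 30, task = 1,
                       cursor_params = cursor_model_params(),
                       eeg_spec = eeg_effect_spec(), seed = 1,
                       config = study_config(), n_trials = NULL,
                       include_eeg = FALSE, eeg_trials_per_subject = 4,
                       n_channels = NULL) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  montage <- make_montage(n_channels %||% config$n_channels)
  per_subject_params <- if (inherits(cursor_params, "cursor_model_params")) {
    rep(list(cursor_params), n_subjects)
  } else cursor_params
  subjects <- vector("list", n_subjects)
  metrics <- list()
  for (s in seq_len(n_subjects)) {
    plan <- build_session_plan(task = task, seed = derive_seed(seed, s * 1000),
                               config = config)
    trials_idx <- seq_len(min(n_trials %||% nrow(plan$trials), nrow(plan$trials)))
    trials <- vector("list", length(trials_idx))
    for (k in trials_idx) {
      row <- plan$trials[k, ]
      traj <- build_trajectory(direction = row$direction,
                               velocity_level = row$velocity_level,
                               seed = row$trajectory_seed, task = task,
                               config = config)
      cursor <- simulate_cursor(traj, per_subject_params[[s]],
                                seed = derive_seed(seed, s * 1000 + k))
      trials[[k]] <- list(trajectory = traj, cursor_y = cursor)
      cond_fun <- condition_labeller(traj, task)
      em <- epoch_metrics(traj$y, cursor, from_hz = config$behavior_rate_hz,
                          to_hz = config$eeg_rate_hz, config = config,
                          condition_of = cond_fun)
      if (nrow(em)) {
        em$subject <- s; em$trial <- k
        metrics[[length(metrics) + 1L]] <- em
      }
    }
    eeg <- NULL
    if (include_eeg) {
      n_eeg <- min(eeg_trials_per_subject %||% length(trials_idx), length(trials_idx))
      eeg <- vector("list", n_eeg)
      for (k in seq_len(n_eeg)) {
        traj <- trials[[k]]$trajectory
        dur <- max(traj$time_s) + 1 / traj$frame_rate
        up <- upsample_coordinates(traj$y, traj$frame_rate, config$eeg_rate_hz)
        pk <- detect_peaks(up$y, config$prominence_fraction_target,
                           config$screen_height_px, times = up$time_s)
        cond_fun <- condition_labeller(traj, task)
        ev <- if (nrow(pk)) {
          data.frame(time_s = pk$time_s,
                     condition = vapply(pk$time_s, cond_fun, character(1)))
        } else data.frame(time_s = numeric(0), condition = character(0))
        cw <- condition_windows_of(traj, task)
        eeg[[k]] <- simulate_eeg(ev, montage, eeg_spec, duration_s = dur + 1,
                                 sfreq = config$eeg_rate_hz, t0 = -1,
                                 condition_windows = cw,
                                 seed = derive_seed(seed, s * 100000 + k))
      }
    }
    subjects[[s]] <- list(plan = plan, trials = trials, eeg = eeg)
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  ground_truth <- list(task = task, seed = seed, n_subjects = n_subjects,
                       cursor_params = per_subject_params,
                       eeg_spec = if (include_eeg) eeg_spec else NULL)
  structure(list(subjects = subjects, metrics = metrics, montage = montage,
                 ground_truth = ground_truth, config = config, task = task),
            class = "synthetic_study")
}

# Returns a function(time_s) -> condition label for one trial: task 1 maps
# peak times to their trajectory segment (random / constant, with the first
# random segment labelled "random"), task 2 to occluded / visible.
condition_labeller <- function(traj, task) {
  if (task == 1) {
    function(t) {
      i <- max(1L, min(length(traj$time_s), round(t * traj$frame_rate) + 1L))
      lab <- traj$segment_labels[i]
      switch(lab, random1 = "random", constant = "constant", lab)
    }
  } else {
    cyc_vis <- 2; cyc <- 4
    function(t) if ((t %% cyc) >= cyc_vis) "occluded" else "visible"
  }
}

# Condition windows (onset/duration/condition) of one trial, matching the
# condition labeller, for band-power injection.
condition_windows_of <- function(traj, task) {
  if (task == 1) {
    labs <- traj$segment_labels
    runs <- rle(labs)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    keep <- runs$values %in% c("random1", "constant")
    data.frame(onset_s = traj$time_s[starts[keep]],
               duration_s = runs$lengths[keep] / traj$frame_rate,
               condition = ifelse(runs$values[keep] == "constant",
                                  "constant", "random"))
  } else {
    dur <- max(traj$time_s)
    occ <- occlusion_intervals(dur, 2, 2)
    vis_starts <- seq(0, dur - 2, by = 4)
    rbind(data.frame(onset_s = occ$start_s, duration_s = occ$end_s - occ$start_s,
                     condition = "occluded"),
          data.frame(onset_s = vis_starts,
                     duration_s = pmin(2, dur - vis_starts),
                     condition = "visible"))
  }
}
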