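# Morlet band power, condition segmentation, sensor-level cluster-based
# permutation statistics, and the source-contrast ratio with density-based
# voxel clustering.

#' EEG epoch container
#'
#' @param data numeric array epochs x channels x samples.
#' @param times_s sample times (strictly increasing).
#' @param sfreq sampling rate in Hz (250 for this study).
#' @param montage data.frame of channel positions (`channel`, `x`, `y`, `z`).
#' @param condition,subject_id optional tags.
#' @param metadata optional per-epoch data.frame.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_s, sfreq, montage = NULL, condition = NULL,
                      subject_id = NULL, metadata = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(times_s))
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (!is.null(montage) && nrow(montage) != dim(data)[2]) {
    stop("montage/channel mismatch: ", nrow(montage), " positions for ",
         dim(data)[2], " channels")
  }
  structure(list(data = data, times_s = times_s, sfreq = sfreq,
                 montage = montage, condition = condition,
                 subject_id = subject_id, metadata = metadata),
            class = "epoch_set")
}

#' Frequencies of a named band
#' @param band `"theta"` (4-7 Hz), `"alpha"` (8-12 Hz) or `"beta"` (13-30 Hz).
#' @return integer frequencies in 1 Hz steps.
#' @export
band_freqs <- function(band = c("theta", "alpha", "beta")) {
  switch(match.arg(band), theta = 4:7, alpha = 8:12, beta = 13:30)
}

# Complex Morlet wavelet at frequency f: Gaussian envelope with
# sd_t = n_cycles / (2 pi f), truncated at +-3.5 sd, unit-sum magnitude.
morlet_wavelet <- function(f, sfreq, n_cycles = 5) {
  sd_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sd_t * sfreq)
  t <- (-half:half) / sfreq
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sd_t^2))
  w / sum(Mod(w))
}

# Linear convolution via FFT, returning the "same"-length centre part.
conv_same <- function(x, w) {
  n <- length(x); nw <- length(w)
  nfft <- stats::nextn(n + nw - 1L, 2)
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                       stats::fft(c(w, rep(0, nfft - nw))), inverse = TRUE) / nfft
  offset <- (nw - 1L) %/% 2L
  full[(offset + 1L):(offset + n)]
}

#' Morlet wavelet band power
#'
#' Time-frequency power from complex Morlet wavelets with a width of 5
#' Gaussians (cycles), evaluated in 1 Hz steps across the requested band.
#'
#' @param epochs an [epoch_set()] or a channels x samples matrix.
#' @param band band name (see [band_freqs()]) or an explicit frequency vector.
#' @param n_cycles wavelet width in cycles (default 5).
#' @param sfreq,times_s required when `epochs` is a bare matrix.
#' @return object of class `tfr`: `power` array epochs x channels x
#'   frequencies x samples (squared magnitude), `freqs`, `times_s`, `band`.
#' @export
morlet_power <- function(epochs, band = "alpha", n_cycles = 5,
                         sfreq = NULL, times_s = NULL) {
  if (is.matrix(epochs)) {
    stopifnot(!is.null(sfreq), !is.null(times_s))
    epochs <- epoch_set(array(epochs, c(1L, dim(epochs))), times_s, sfreq)
  }
  stopifnot(inherits(epochs, "epoch_set"))
  freqs <- if (is.character(band)) band_freqs(band) else as.numeric(band)
  sfreq <- epochs$sfreq
  n_samp <- dim(epochs$data)[3]
  w_list <- lapply(freqs, morlet_wavelet, sfreq = sfreq, n_cycles = n_cycles)
  too_long <- vapply(w_list, length, 1L) > n_samp
  if (any(too_long)) {
    stop("epoch too short for ", n_cycles, "-cycle wavelet at ",
         min(freqs[too_long]), " Hz (needs ", max(vapply(w_list, length, 1L)),
         " samples, have ", n_samp, ")")
  }
  ne <- dim(epochs$data)[1]; nc <- dim(epochs$data)[2]
  power <- array(NA_real_, c(ne, nc, length(freqs), n_samp))
  # batch the convolutions: one column per epoch x channel trace
  nw_max <- max(vapply(w_list, length, 1L))
  nfft <- stats::nextn(n_samp + nw_max - 1L, 2)
  X <- matrix(0, nfft, ne * nc)
  X[seq_len(n_samp), ] <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = n_samp)
  FX <- stats::mvfft(X)
  for (fi in seq_along(freqs)) {
    w <- w_list[[fi]]
    FW <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(FX * FW, inverse = TRUE) / nfft
    offset <- (length(w) - 1L) %/% 2L
    pw <- Mod(conv[(offset + 1L):(offset + n_samp), , drop = FALSE])^2
    power[, , fi, ] <- aperm(array(pw, c(n_samp, nc, ne)), c(3, 2, 1))
  }
  structure(list(power = power, freqs = freqs, times_s = epochs$times_s,
                 sfreq = sfreq, band = if (is.character(band)) band else "custom",
                 montage = epochs$montage, condition = epochs$condition,
                 subject_id = epochs$subject_id),
            class = "tfr")
}

#' Baseline-correct a time-frequency representation
#'
#' Expresses power relative to the mean power in the pre-trial baseline window
#' (-750 ms to trial start by default), per epoch, channel and frequency.
#' Default mode is decibel change, `10 * log10(power / baseline)`; a plain
#' ratio mode is available.
#'
#' @param tfr a `tfr` from [morlet_power()].
#' @param window baseline window in seconds (must lie inside the epoch).
#' @param mode `"db"` or `"ratio"`.
#' @return the corrected `tfr`.
#' @export
baseline_correct <- function(tfr, window = c(-0.75, 0), mode = c("db", "ratio")) {
  mode <- match.arg(mode)
  sel <- tfr$times_s >= window[1] & tfr$times_s <= window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  base <- apply(tfr$power[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  if (any(base <= 0)) stop("zero or negative baseline power: cannot normalize")
  norm <- sweep(tfr$power, c(1, 2, 3), base, "/")
  tfr$power <- if (mode == "db") 10 * log10(norm) else norm
  tfr$baseline_window_s <- window
  tfr$baseline_mode <- mode
  tfr
}

# Subset a tfr in time; returns the tfr restricted to [from, to).
tfr_window <- function(tfr, from, to) {
  sel <- tfr$times_s >= from & tfr$times_s < to
  tfr$power <- tfr$power[, , , sel, drop = FALSE]
  tfr$times_s <- tfr$times_s[sel]
  tfr
}

#' Segment a trial-level TFR into the condition windows
#'
#' Task 1 contrasts the random and the constant trajectory segment over two
#' intervals: the first interval takes the initial 500 ms of each segment; the
#' second interval compares 500-3000 ms of the random segment to 0-2500 ms of
#' the constant segment (both 2500 ms). Task 2 alternates 2-s visible and 2-s
#' occluded windows from trial start, beginning visible. Window lengths are
#' equal within a contrast (trimmed to the shorter if rounding differs).
#'
#' @param tfr trial-level `tfr` spanning the trial (times relative to trial
#'   start).
#' @param task 1 or 2.
#' @param random_onset_s,constant_onset_s segment onsets for task 1.
#' @param interval `"first"` or `"second"` (task 1 only).
#' @param trial_duration_s trial length (task 2).
#' @param visible_s,occluded_s occlusion cycle (task 2).
#' @return named list of `tfr` windows: task 1 `list(random=, constant=)`;
#'   task 2 `list(occluded=, visible=)` with the windows of each state
#'   concatenated along time.
#' @export
segment_conditions <- function(tfr, task, random_onset_s = 0, constant_onset_s = NULL,
                               interval = c("first", "second"),
                               trial_duration_s = NULL,
                               visible_s = 2, occluded_s = 2) {
  if (task == 1) {
    interval <- match.arg(interval)
    if (is.null(constant_onset_s)) stop("constant_onset_s required for task 1")
    win <- if (interval == "first") {
      list(random = c(random_onset_s, random_onset_s + 0.5),
           constant = c(constant_onset_s, constant_onset_s + 0.5))
    } else {
      list(random = c(random_onset_s + 0.5, random_onset_s + 3.0),
           constant = c(constant_onset_s, constant_onset_s + 2.5))
    }
    out <- lapply(win, function(w) tfr_window(tfr, w[1], w[2]))
  } else {
    if (is.null(trial_duration_s)) trial_duration_s <- max(tfr$times_s)
    cyc <- visible_s + occluded_s
    occ <- occlusion_intervals(trial_duration_s, visible_s, occluded_s)
    vis_starts <- seq(0, trial_duration_s - visible_s, by = cyc)
    take <- function(starts, len) {
      parts <- lapply(starts, function(s0) tfr_window(tfr, s0, s0 + len))
      parts <- parts[vapply(parts, function(p) length(p$times_s), 1L) > 0]
      if (!length(parts)) stop("trial shorter than the required windows")
      joined <- parts[[1]]
      if (length(parts) > 1) {
        joined$power <- do.call(function(...) abind4(...), lapply(parts, `[[`, "power"))
        joined$times_s <- unlist(lapply(parts, `[[`, "times_s"))
      }
      joined
    }
    out <- list(occluded = take(occ$start_s, occluded_s),
                visible = take(vis_starts, visible_s))
  }
  n_min <- min(vapply(out, function(p) dim(p$power)[4], 1L))
  if (n_min < 1L) stop("trial shorter than the required windows")
  lapply(out, function(p) {
    p$power <- p$power[, , , seq_len(n_min), drop = FALSE]
    p$times_s <- p$times_s[seq_len(n_min)]
    p
  })
}

# bind 4-d arrays along the 4th margin
abind4 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n4 <- sum(vapply(parts, function(p) dim(p)[4], 1L))
  out <- array(NA_real_, c(d[1:3], n4))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[4]
    out[, , , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

#' Channel adjacency from montage positions
#'
#' Two channels are neighbours when their 3-d distance is below
#' `factor` times the median nearest-neighbour distance of the montage.
#'
#' @param montage data.frame with `x`, `y`, `z` unit-sphere positions.
#' @param factor distance threshold multiplier (default 1.6).
#' @return symmetric logical adjacency matrix (FALSE on the diagonal).
#' @export
channel_adjacency <- function(montage, factor = 1.6) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1, min))
  adj <- d <= thr
  diag(adj) <- FALSE
  adj
}

# Connected components of supra-threshold points under combined
# channel-adjacency x grid-contiguity neighbourhood. `pts` is a matrix with
# columns ch, f, t (f constant = 1 for pure time grids). Returns an integer
# component label per point.
cluster_points <- function(pts, adjacency) {
  np <- nrow(pts)
  if (np == 0L) return(integer(0))
  labels <- integer(np)
  # hash map from (ch, f, t) to point index for O(1) neighbour lookup
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = ",")
  lookup <- new.env(hash = TRUE, size = np * 2L)
  for (i in seq_len(np)) assign(key[i], i, envir = lookup)
  get_idx <- function(ch, f, t) {
    k <- paste(ch, f, t, sep = ",")
    if (exists(k, envir = lookup, inherits = FALSE)) get(k, envir = lookup) else 0L
  }
  comp <- 0L
  for (start in seq_len(np)) {
    if (labels[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      ch <- pts[i, 1]; f <- pts[i, 2]; t <- pts[i, 3]
      nb <- c(get_idx(ch, f, t - 1L), get_idx(ch, f, t + 1L),
              get_idx(ch, f - 1L, t), get_idx(ch, f + 1L, t))
      for (och in which(adjacency[ch, ])) nb <- c(nb, get_idx(och, f, t))
      nb <- nb[nb > 0L]
      fresh <- nb[labels[nb] == 0L]
      labels[fresh] <- comp
      queue <- c(queue, fresh)
    }
  }
  labels
}

# Paired t statistics for sign-flipped differences, fully vectorised across
# permutations: for sign matrix S (n x B) and difference matrix D (n x P),
# the per-point mean is t(S) D / n and the second moment colSums(D^2)/n is
# flip-invariant.
flip_t_matrix <- function(D, S) {
  n <- nrow(D)
  M <- crossprod(S, D) / n                     # B x P means
  ssq <- colSums(D^2) / n                      # length P, flip-invariant
  V <- sweep(-M^2, 2, ssq, "+") * n / (n - 1)  # unbiased variance per cell
  V[V < .Machine$double.eps] <- .Machine$double.eps
  M / sqrt(V / n)
}

#' Cluster-based permutation test for paired condition contrasts
#'
#' Pointwise paired t-tests over a channels x (frequency x) time grid,
#' thresholded at `cluster_alpha` (two-sided); supra-threshold points are
#' grouped into spatio-temporally contiguous clusters (spatial neighbours from
#' the channel adjacency, plus contiguity in time and frequency), each scored
#' by its summed t values. The null distribution of the per-permutation
#' maximum cluster sum is built from within-subject sign flips of the paired
#' differences; cluster p values compare against the matching polarity's
#' extremes with add-one smoothing.
#'
#' @param cond_a,cond_b subject-level arrays, subjects x channels x times or
#'   subjects x channels x frequencies x times.
#' @param adjacency channel adjacency matrix from [channel_adjacency()].
#' @param n_permutations Monte-Carlo iterations (1000 for time-frequency,
#'   3000 for ERP contrasts).
#' @param cluster_alpha two-sided threshold for the pointwise tests.
#' @param seed optional seed.
#' @param times_s sample times used to report cluster onsets/offsets.
#' @param chunk permutations processed per block (memory control).
#' @return list of clusters, each a list with `polarity`, `t_sum`, `p`,
#'   `members` (data.frame channel / freq / time indices and t values),
#'   `onset_s`, `offset_s`, `duration_samples`, `channels`; empty list when no
#'   point is supra-threshold. Attributes carry the observed t field and the
#'   permutation extremes.
#' @export
cluster_permutation_test <- function(cond_a, cond_b, adjacency,
                                     n_permutations = 1000, cluster_alpha = 0.001,
                                     seed = NULL, times_s = NULL, chunk = 250L) {
  da <- dim(cond_a)
  if (!identical(da, dim(cond_b))) stop("condition arrays differ in shape")
  if (length(da) == 3L) {
    cond_a <- array(cond_a, c(da[1], da[2], 1L, da[3]))
    cond_b <- array(cond_b, c(da[1], da[2], 1L, da[3]))
    da <- dim(cond_a)
  }
  n_sub <- da[1]; n_ch <- da[2]; n_f <- da[3]; n_t <- da[4]
  if (n_sub < 2L) stop("need at least 2 subjects")
  if (nrow(adjacency) != n_ch) stop("adjacency does not match channel count")
  if (is.null(times_s)) times_s <- seq_len(n_t)

  P <- n_ch * n_f * n_t
  D <- matrix(aperm(cond_a - cond_b, c(1, 2, 3, 4)), nrow = n_sub)  # n x P
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n_sub - 1)

  grid_of <- function(p_idx) {
    p0 <- p_idx - 1L
    ch <- p0 %% n_ch + 1L
    rest <- p0 %/% n_ch
    f <- rest %% n_f + 1L
    t <- rest %/% n_f + 1L
    cbind(ch = ch, f = f, t = t)
  }

  # observed t field and clusters
  t_obs <- drop(flip_t_matrix(D, matrix(1, n_sub, 1)))
  observed_clusters <- function(tv) {
    res <- list()
    for (pol in c("positive", "negative")) {
      sel <- if (pol == "positive") which(tv > tcrit) else which(tv < -tcrit)
      if (!length(sel)) next
      pts <- grid_of(sel)
      labs <- cluster_points(pts, adjacency)
      for (cl in unique(labs)) {
        mem <- sel[labs == cl]
        mp <- pts[labs == cl, , drop = FALSE]
        res[[length(res) + 1L]] <- list(
          polarity = pol,
          t_sum = sum(tv[mem]),
          members = data.frame(channel = mp[, 1], freq = mp[, 2], time = mp[, 3],
                               t = tv[mem]),
          onset_s = times_s[min(mp[, 3])], offset_s = times_s[max(mp[, 3])],
          duration_samples = max(mp[, 3]) - min(mp[, 3]) + 1L,
          channels = sort(unique(mp[, 1])))
      }
    }
    res
  }
  clusters <- observed_clusters(t_obs)

  max_pos <- rep(0, n_permutations)
  min_neg <- rep(0, n_permutations)
  if (length(clusters)) {
    with_seed(seed, {
      done <- 0L
      while (done < n_permutations) {
        b <- min(chunk, n_permutations - done)
        S <- matrix(sample(c(-1, 1), n_sub * b, replace = TRUE), n_sub, b)
        Tm <- flip_t_matrix(D, S)
        for (r in seq_len(b)) {
          tv <- Tm[r, ]
          pos <- which(tv > tcrit)
          if (length(pos)) {
            labs <- cluster_points(grid_of(pos), adjacency)
            max_pos[done + r] <- max(tapply(tv[pos], labs, sum))
          }
          neg <- which(tv < -tcrit)
          if (length(neg)) {
            labs <- cluster_points(grid_of(neg), adjacency)
            min_neg[done + r] <- min(tapply(tv[neg], labs, sum))
          }
        }
        done <- done + b
      }
    })
    # two-sided reference: the permutation maximum of |cluster sum| across
    # both polarities, so the family-wise error is controlled at alpha overall
    max_abs <- pmax(max_pos, -min_neg)
    for (i in seq_along(clusters)) {
      exceed <- sum(max_abs >= abs(clusters[[i]]$t_sum))
      clusters[[i]]$p <- (1 + exceed) / (n_permutations + 1)
    }
  }
  attr(clusters, "t_obs") <- array(t_obs, c(n_ch, n_f, n_t))
  attr(clusters, "perm_max_pos") <- max_pos
  attr(clusters, "perm_min_neg") <- min_neg
  attr(clusters, "tcrit") <- tcrit
  clusters
}

#' Normalized source-power contrast
#'
#' Elementwise (p1 - p2) / (p1 + p2): a bounded, noise-robust contrast of two
#' voxel power maps. Voxels where both powers are zero map to 0 (their count
#' is reported in an attribute).
#'
#' @param power_a,power_b non-negative voxel power vectors on the same grid.
#' @return ratio vector in \[-1, 1\] with attribute `n_zero_sum`.
#' @export
normalized_contrast <- function(power_a, power_b) {
  if (length(power_a) != length(power_b)) stop("voxel grid mismatch")
  if (any(power_a < 0) || any(power_b < 0)) stop("powers must be non-negative")
  s <- power_a + power_b
  r <- ifelse(s > 0, (power_a - power_b) / s, 0)
  attr(r, "n_zero_sum") <- sum(s == 0)
  r
}

# Plain DBSCAN on a small point set: eps-neighbourhood density clustering with
# noise label 0.
dbscan_fit <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Density-based clustering of extreme contrast voxels
#'
#' Selects the most positive (or most negative) `tail_fraction` of the ratio
#' distribution and groups the selected voxels with DBSCAN, using a search
#' radius of `eps_factor` times the voxel edge length.
#'
#' @param coords voxel centres, matrix or data.frame with 3 columns (mm).
#' @param ratio normalized contrast per voxel (see [normalized_contrast()]).
#' @param voxel_size_mm voxel edge length.
#' @param tail_fraction fraction of voxels selected (default 0.01).
#' @param eps_factor neighbourhood radius in voxel edge lengths (default 1.5).
#' @param direction `"positive"` or `"negative"` tail.
#' @param min_pts DBSCAN core-point threshold (default 5).
#' @return list: `selected` (voxel indices), `labels` (cluster id per selected
#'   voxel, 0 = noise), `clusters` (list with member indices and centroid).
#' @export
dbscan_voxel_clusters <- function(coords, ratio, voxel_size_mm,
                                  tail_fraction = 0.01, eps_factor = 1.5,
                                  direction = c("positive", "negative"),
                                  min_pts = 5) {
  direction <- match.arg(direction)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(ratio), voxel_size_mm > 0)
  if (!length(ratio)) stop("empty voxel selection")
  sel <- if (direction == "positive") {
    which(ratio >= stats::quantile(ratio, 1 - tail_fraction))
  } else {
    which(ratio <= stats::quantile(ratio, tail_fraction))
  }
  if (!length(sel)) stop("empty voxel selection")
  labels <- dbscan_fit(coords[sel, , drop = FALSE],
                       eps = eps_factor * voxel_size_mm, min_pts = min_pts)
  clusters <- lapply(sort(unique(labels[labels > 0L])), function(cl) {
    members <- sel[labels == cl]
    list(members = members,
         centroid = colMeans(coords[members, , drop = FALSE]),
         n_voxels = length(members),
         mean_ratio = mean(ratio[members]))
  })
  list(selected = sel, labels = labels, clusters = clusters,
       direction = direction, eps = eps_factor * voxel_size_mm)
}
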