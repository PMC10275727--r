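# Direction-change-locked ERP analysis: epoching, spherical-spline current
# source density, trial-count weighting, time-domain cluster statistics,
# cluster selection, peak-latency contrast, and the ERP-by-performance
# vincentile matrix.

#' Epoch continuous EEG around trajectory peaks
#'
#' Cuts one epoch per target direction change, spanning -500 to +750 ms at
#' 250 Hz (313 samples), and subtracts the mean of the first 500 ms
#' (the pre-peak baseline) per channel and epoch. Peaks whose window would
#' cross a recording edge are skipped and counted.
#'
#' @param eeg list with `data` (channels x samples matrix), `sfreq`, and
#'   optionally `t0` (time of the first sample, default 0) and `montage`.
#' @param peak_times_s trajectory peak times (seconds, same clock as the
#'   recording).
#' @param window epoch window in seconds.
#' @param baseline baseline window in seconds.
#' @param metadata optional data.frame with one row per peak (condition,
#'   epoch_error_px, pursuit_latency_s, valid, ...), carried with the epochs.
#' @return an [epoch_set()]; attribute `n_skipped` counts edge-dropped peaks.
#' @export
epoch_around_peaks <- function(eeg, peak_times_s, window = c(-0.5, 0.75),
                               baseline = c(-0.5, 0), metadata = NULL) {
  fs <- eeg$sfreq
  t0 <- eeg$t0 %||% 0
  offsets <- seq.int(round(window[1] * fs), floor(window[2] * fs))
  times <- offsets / fs
  n_samp <- ncol(eeg$data)
  centers <- round((peak_times_s - t0) * fs) + 1L
  ok <- centers + offsets[1] >= 1L & centers + offsets[length(offsets)] <= n_samp
  n_skipped <- sum(!ok)
  centers <- centers[ok]
  if (!is.null(metadata)) metadata <- metadata[ok, , drop = FALSE]
  if (!length(centers)) stop("no peak with a full epoch window inside the recording")
  dat <- array(NA_real_, c(length(centers), nrow(eeg$data), length(offsets)))
  bsel <- times >= baseline[1] & times <= baseline[2]
  for (e in seq_along(centers)) {
    seg <- eeg$data[, centers[e] + offsets, drop = FALSE]
    seg <- seg - rowMeans(seg[, bsel, drop = FALSE])
    dat[e, , ] <- seg
  }
  out <- epoch_set(dat, times, fs, montage = eeg$montage, metadata = metadata)
  attr(out, "n_skipped") <- n_skipped
  out
}

# Legendre polynomials P_1..P_n evaluated at matrix X (entries in [-1, 1]),
# via the three-term recurrence; returns a list of matrices.
legendre_terms <- function(X, n_terms) {
  out <- vector("list", n_terms)
  Pm1 <- matrix(1, nrow(X), ncol(X))   # P_0
  P <- X                               # P_1
  out[[1]] <- P
  for (n in 1:(n_terms - 1)) {
    Pn1 <- ((2 * n + 1) * X * P - n * Pm1) / (n + 1)
    Pm1 <- P
    P <- Pn1
    out[[n + 1]] <- P
  }
  out
}

# Spherical-spline G and H matrices (Perrin-style surface Laplacian) for unit
# head radius; m is the spline stiffness, n_terms the Legendre truncation.
csd_gh <- function(pos, m = 4, n_terms = 50) {
  pos <- pos / sqrt(rowSums(pos^2))
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  Pn <- legendre_terms(cosang, n_terms)
  G <- H <- matrix(0, nrow(pos), nrow(pos))
  for (n in seq_len(n_terms)) {
    G <- G + (2 * n + 1) / (n * (n + 1))^m * Pn[[n]]
    H <- H + (2 * n + 1) / (n * (n + 1))^(m - 1) * Pn[[n]]
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

#' Current source density via spherical splines
#'
#' Surface-Laplacian transform of scalp potentials (sharpening topographies):
#' a spherical spline is fitted per sample with stiffness `m = 4` and
#' regularization `lambda = 1e-5` on a normalized head radius, and its
#' Laplacian is evaluated at the electrodes. The transform is linear and maps
#' a spatially uniform potential to zero.
#'
#' @param epochs an [epoch_set()] (>= 16 channels) or a channels x samples
#'   matrix (then pass `montage`).
#' @param montage data.frame with unit-sphere `x`, `y`, `z` per channel.
#' @param m spline stiffness order.
#' @param lambda ridge regularization added to the diagonal of G.
#' @param n_legendre number of Legendre terms.
#' @return the input with data replaced by CSD values.
#' @export
csd_transform <- function(epochs, montage = NULL, m = 4, lambda = 1e-5,
                          n_legendre = 50) {
  bare <- is.matrix(epochs)
  if (!bare) montage <- montage %||% epochs$montage
  if (is.null(montage)) stop("montage with spherical coordinates required")
  pos <- as.matrix(montage[, c("x", "y", "z")])
  if (nrow(pos) < 16L) stop("CSD needs at least 16 channels")
  if (qr(sweep(pos, 2, colMeans(pos)))$rank < 3L) stop("degenerate montage geometry")
  gh <- csd_gh(pos, m = m, n_terms = n_legendre)
  Ginv <- solve(gh$G + diag(lambda, nrow(pos)))
  TC <- rowSums(Ginv)
  sgi <- sum(TC)
  apply_csd <- function(V) {
    Cp <- Ginv %*% V
    c0 <- colSums(Cp) / sgi
    gh$H %*% (Cp - outer(TC, c0))
  }
  if (bare) return(apply_csd(epochs))
  for (e in seq_len(dim(epochs$data)[1])) {
    epochs$data[e, , ] <- apply_csd(epochs$data[e, , ])
  }
  epochs$units <- "CSD"
  epochs
}

#' Trial-count weights for grand averaging
#'
#' Weight per subject = median epoch count across subjects divided by that
#' subject's count; multiplied onto each subject's average before grand
#' averaging so subjects with few epochs do not dominate. Equal counts give
#' all-one weights.
#'
#' @param counts epochs per subject (>= 1 each).
#' @return numeric weights, same length as `counts`.
#' @export
weight_by_trial_count <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 1)) stop("zero epoch count")
  stats::median(counts) / counts
}

#' Time-domain cluster permutation test with the electrode-extent rule
#'
#' Runs [cluster_permutation_test()] over channels x time (3000 permutations
#' by default) and discards clusters that never reach `min_neighbors`
#' electrodes at any single time point.
#'
#' @param cond_a,cond_b subject-level weighted ERPs, subjects x channels x
#'   times.
#' @param adjacency channel adjacency matrix.
#' @param n_permutations,cluster_alpha,seed,times_s passed through.
#' @param min_neighbors minimum simultaneous electrode extent (default 4).
#' @return cluster list as in [cluster_permutation_test()].
#' @export
erp_cluster_test <- function(cond_a, cond_b, adjacency, n_permutations = 3000,
                             cluster_alpha = 0.001, min_neighbors = 4,
                             seed = NULL, times_s = NULL) {
  clusters <- cluster_permutation_test(cond_a, cond_b, adjacency,
                                       n_permutations = n_permutations,
                                       cluster_alpha = cluster_alpha,
                                       seed = seed, times_s = times_s)
  keep <- vapply(clusters, function(cl) {
    max(tapply(cl$members$channel, cl$members$time, function(x) length(unique(x)))) >=
      min_neighbors
  }, logical(1))
  out <- clusters[keep]
  attributes(out) <- c(attributes(out), attributes(clusters)[c(
    "t_obs", "perm_max_pos", "perm_min_neg", "tcrit")])
  attr(out, "n_dropped_extent") <- sum(!keep)
  out
}

#' Select clusters for further analysis
#'
#' Keeps at most the three largest clusters per polarity by absolute t-value
#' sum (the scree-plot elbow rule), then drops clusters that are shorter than
#' five samples or whose onset falls more than 300 ms after the direction
#' change (later activity mixes with the following direction change).
#'
#' @param clusters cluster list from [erp_cluster_test()].
#' @param max_per_polarity keep at most this many per polarity (default 3).
#' @param min_duration_samples minimum temporal extent (default 5).
#' @param max_onset_s latest admissible onset (default 0.3 s).
#' @return the retained subset, ordered by decreasing |t_sum|.
#' @export
select_clusters <- function(clusters, max_per_polarity = 3,
                            min_duration_samples = 5, max_onset_s = 0.3) {
  if (!length(clusters)) return(clusters)
  ord <- order(-abs(vapply(clusters, `[[`, numeric(1), "t_sum")))
  clusters <- clusters[ord]
  pol <- vapply(clusters, `[[`, character(1), "polarity")
  keep_rank <- unlist(lapply(split(seq_along(clusters), pol), function(idx) {
    idx[seq_len(min(length(idx), max_per_polarity))]
  }), use.names = FALSE)
  clusters <- clusters[sort(keep_rank)]
  keep <- vapply(clusters, function(cl) {
    cl$duration_samples >= min_duration_samples && cl$onset_s <= max_onset_s
  }, logical(1))
  clusters[keep]
}

#' Peak-latency contrast between two conditions
#'
#' Finds the positive-peak latency of each subject's electrode-averaged ERP
#' inside the search window (a local maximum; subjects without one are
#' excluded and counted) and compares the two conditions with a paired
#' two-tailed t-test and Cohen's d.
#'
#' @param erp_a,erp_b subjects x times matrices (same subjects, same order).
#' @param times_s sample times.
#' @param window search window in seconds (default 0.2-0.45 s, bracketing the
#'   component of interest).
#' @return list: `t`, `df`, `p`, `d`, `mean_latency_a_s`, `mean_latency_b_s`,
#'   `latencies_a_s`, `latencies_b_s`, `n_excluded`.
#' @export
peak_latency_contrast <- function(erp_a, erp_b, times_s, window = c(0.2, 0.45)) {
  stopifnot(identical(dim(erp_a), dim(erp_b)))
  sel <- which(times_s >= window[1] & times_s <= window[2])
  if (length(sel) < 3L) stop("search window too narrow")
  find_lat <- function(x) {
    w <- x[sel]
    pk <- local_maxima(w)
    # window-edge maxima only count if they are maxima of the full series
    if (!length(pk)) {
      i <- which.max(w)
      full_i <- sel[i]
      if (full_i > 1L && full_i < length(x) &&
          x[full_i] >= x[full_i - 1L] && x[full_i] >= x[full_i + 1L]) pk <- i
    }
    if (!length(pk)) return(NA_real_)
    times_s[sel[pk[which.max(w[pk])]]]
  }
  lat_a <- apply(erp_a, 1, find_lat)
  lat_b <- apply(erp_b, 1, find_lat)
  ok <- is.finite(lat_a) & is.finite(lat_b)
  if (sum(ok) < 2L) stop("fewer than 2 subjects with a peak in the window")
  d <- lat_a[ok] - lat_b[ok]
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero-variance latency differences")
  n <- sum(ok)
  t_val <- mean(d) / (sd_d / sqrt(n))
  list(t = t_val, df = n - 1, p = 2 * stats::pt(-abs(t_val), n - 1),
       d = mean(d) / sd_d,
       mean_latency_a_s = mean(lat_a[ok]), mean_latency_b_s = mean(lat_b[ok]),
       latencies_a_s = lat_a, latencies_b_s = lat_b, n_excluded = sum(!ok))
}

#' ERP-by-performance vincentile matrix
#'
#' Links single-epoch ERPs to tracking performance: epochs with a valid
#' pursuit latency are averaged over a cluster's electrodes, binned into 10
#' behavioral vincentiles per subject and condition, and the vincentile-mean
#' ERP is averaged inside ten 50-ms time bins from 50 to 550 ms after the
#' direction change (12-13 samples per bin at 250 Hz). Each of the 100
#' vincentile-time cells is tested between conditions with a bootstrap paired
#' t-test; BH-FDR runs across the 100 p values and Cohen's d is reported per
#' cell.
#'
#' @param epochs_by_subject named list (one entry per subject) of lists with
#'   elements `a` and `b`, each a list with `data` (epochs x channels x
#'   samples), `measure` (behavioral value per epoch) and `valid` (logical per
#'   epoch).
#' @param times_s epoch sample times (seconds relative to the peak).
#' @param cluster_electrodes electrode indices to average.
#' @param k number of vincentiles (10).
#' @param n_bins,bin_start_s,bin_width_s time binning (10 bins of 50 ms from
#'   50 ms).
#' @param n_boot,alpha,q test parameters.
#' @param seed optional seed.
#' @return object of class `vincentile_bin_matrix`: arrays `values`
#'   (subject x condition(2) x vincentile x bin), `t`, `p`, `d` (k x n_bins),
#'   `fdr_mask`, `significant`, counts of skipped cells.
#' @export
erp_vincentile_matrix <- function(epochs_by_subject, times_s, cluster_electrodes,
                                  k = 10, n_bins = 10, bin_start_s = 0.05,
                                  bin_width_s = 0.05, n_boot = 5000,
                                  alpha = 0.001, q = 0.05, seed = NULL) {
  n_sub <- length(epochs_by_subject)
  bin_of <- function(t) {
    b <- floor((t - bin_start_s) / bin_width_s) + 1L
    b[t < bin_start_s | b > n_bins] <- NA_integer_
    b
  }
  bins <- bin_of(times_s)
  vals <- array(NA_real_, c(n_sub, 2L, k, n_bins),
                dimnames = list(names(epochs_by_subject), c("a", "b"), NULL, NULL))
  for (s in seq_len(n_sub)) {
    for (ci in 1:2) {
      cond <- epochs_by_subject[[s]][[c("a", "b")[ci]]]
      ok <- cond$valid & is.finite(cond$measure)
      if (sum(ok) < k) next
      sig <- cond$data[ok, cluster_electrodes, , drop = FALSE]
      sig <- apply(sig, c(1, 3), mean)                       # epochs x samples
      vbin <- vincentile_assign(cond$measure[ok], k = k)
      for (v in seq_len(k)) {
        avg <- colMeans(sig[vbin == v, , drop = FALSE])
        vals[s, ci, v, ] <- as.numeric(tapply(avg, bins, mean))[seq_len(n_bins)]
      }
    }
  }
  t_m <- p_m <- d_m <- matrix(NA_real_, k, n_bins)
  n_skipped <- 0L
  cell <- 0L
  for (v in seq_len(k)) {
    for (b in seq_len(n_bins)) {
      cell <- cell + 1L
      av <- vals[, 1, v, b]; bv <- vals[, 2, v, b]
      ok <- is.finite(av) & is.finite(bv)
      if (sum(ok) < 2L) { n_skipped <- n_skipped + 1L; next }
      res <- bootstrap_paired_test(av[ok], bv[ok], n_boot = n_boot,
                                   seed = if (is.null(seed)) NULL else derive_seed(seed, cell))
      t_m[v, b] <- res$t; p_m[v, b] <- res$p; d_m[v, b] <- res$d
    }
  }
  mask <- matrix(fdr_correct(as.numeric(p_m), q = q), k, n_bins)
  structure(list(values = vals, t = t_m, p = p_m, d = d_m,
                 fdr_mask = mask, significant = mask & p_m <= alpha,
                 n_cells = k * n_bins, n_skipped = n_skipped,
                 samples_per_bin = as.numeric(table(bins)),
                 bin_start_s = bin_start_s, bin_width_s = bin_width_s),
            class = "vincentile_bin_matrix")
}
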