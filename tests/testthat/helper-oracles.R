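# Independent oracles used by the unit tests. These deliberately use naive
# algorithms (double loops, brute-force scans) so they stay independent of the
# implementation paths they check.

# Naive O(n^2) sample-entropy oracle: count template pairs by double loop.
sampen_oracle <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  a <- 0L
  b <- 0L
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (j == i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        b <- b + 1L
        if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1L
      }
    }
  }
  # each unordered pair counted twice; ratio unaffected
  -log(a / b)
}

# Brute-force lagged cross-correlation argmax (in frames, cursor vs target).
xcorr_peak_lag <- function(target, cursor, max_lag) {
  cors <- vapply(0:max_lag, function(k) {
    n <- length(target)
    stats::cor(target[1:(n - k)], cursor[(k + 1):n])
  }, numeric(1))
  which.max(cors) - 1L
}

# Brute-force greedy bipartite check: is a valid one-to-one matching with the
# same pairs reproducible from first principles?
brute_force_match <- function(traj_times, traj_dirs, purs_times, purs_dirs,
                              window = c(0.08, 0.30)) {
  used <- rep(FALSE, length(purs_times))
  out <- rep(NA_integer_, length(traj_times))
  for (i in order(traj_times)) {
    lat <- purs_times - traj_times[i]
    cand <- which(!used & purs_dirs == traj_dirs[i] &
                    lat >= window[1] & lat <= window[2])
    if (length(cand)) {
      j <- cand[which.min(purs_times[cand])]
      used[j] <- TRUE
      out[i] <- j
    }
  }
  out
}

# Welch-style band power from the raw periodogram.
band_power <- function(x, sfreq, f_lo, f_hi) {
  n <- length(x)
  pxx <- Mod(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * sfreq / n
  mean(pxx[f >= f_lo & f <= f_hi])
}

# Small helper: a simulated task-1 study scaled for unit tests.
tiny_study <- function(n_subjects = 3, n_trials = 4, seed = 7, ...) {
  make_study(n_subjects = n_subjects, task = 1, seed = seed,
             n_trials = n_trials, ...)
}
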