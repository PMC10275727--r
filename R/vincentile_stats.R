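# Vincentile binning, bootstrap paired condition contrasts with FDR control,
# and cross-sorting of the two tracking-performance measures.

#' Vincentile bin means
#'
#' Sorts the values ascending and partitions them into `k` equal-populated
#' bins (when the count is not divisible by `k`, the remainder is assigned one
#' extra value per bin starting from the lowest bins), returning the mean of
#' each bin. Ties keep their input order (stable sort).
#'
#' @param values numeric vector, at least `k` values.
#' @param k number of bins (default 10).
#' @param label used in error messages (e.g. "subject 3 / constant").
#' @return numeric vector of `k` non-decreasing bin means.
#' @export
vincentilize <- function(values, k = 10, label = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < k) {
    stop("fewer than ", k, " values for vincentile binning",
         if (!is.null(label)) paste0(" (", label, ")") else "")
  }
  sorted <- values[order(values)]            # stable
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(seq_len(k), times = sizes)
  as.numeric(tapply(sorted, bin, mean))
}

#' Vincentile bin assignment
#'
#' Assigns each value to its vincentile by rank, with the same remainder rule
#' as [vincentilize()]; returns an integer bin id per input element (in input
#' order).
#' @param values numeric vector, at least `k` values.
#' @param k number of bins.
#' @export
vincentile_assign <- function(values, k = 10) {
  n <- length(values)
  if (n < k) stop("fewer than ", k, " values for vincentile assignment")
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin_sorted <- rep(seq_len(k), times = sizes)
  out <- integer(n)
  out[order(values)] <- bin_sorted
  out
}

#' Bootstrap paired two-tailed t-test
#'
#' Computes the observed paired t statistic, then resamples subjects with
#' replacement from the H0-centred differences (`method = "centered_t"`,
#' default) and takes the two-tailed proportion of bootstrap t statistics at
#' least as extreme, with add-one smoothing. A percentile-of-differences
#' variant is available. Cohen's d is the paired effect size
#' mean(diff) / sd(diff).
#'
#' @param a,b equal-length paired condition vectors (one value per subject).
#' @param n_boot number of bootstrap samples (default 5000).
#' @param seed optional seed.
#' @param method `"centered_t"` or `"percentile"`.
#' @return list: `t`, `p`, `d`, `n`, `n_boot`, `method`.
#' @export
bootstrap_paired_test <- function(a, b, n_boot = 5000, seed = NULL,
                                  method = c("centered_t", "percentile")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero-variance differences: effect size undefined")
  t_obs <- mean(d) / (sd_d / sqrt(n))
  cohen_d <- mean(d) / sd_d

  p <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    if (method == "centered_t") {
      dc <- d - mean(d)
      m <- matrix(dc[idx], nrow = n)
      means <- colMeans(m)
      vars <- pmax(0, (colSums(m^2) - n * means^2) / (n - 1))
      t_star <- ifelse(vars > 0, means / sqrt(vars / n), Inf)
      (1 + sum(abs(t_star) >= abs(t_obs))) / (n_boot + 1)
    } else {
      means <- colMeans(matrix(d[idx], nrow = n))
      lower <- (1 + sum(means <= 0)) / (n_boot + 1)
      upper <- (1 + sum(means >= 0)) / (n_boot + 1)
      min(1, 2 * min(lower, upper))
    }
  })
  list(t = t_obs, p = p, d = cohen_d, n = n, n_boot = n_boot, method = method)
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control at level `q`.
#' @param p_values vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical mask, TRUE where the BH-adjusted p value is at most `q`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Vincentile table for one measure
#'
#' Bins one behavioral measure into `k` vincentiles per subject and condition.
#'
#' @param data data.frame with columns `subject`, `condition`, and the
#'   measure column.
#' @param measure column name to bin (`"epoch_error_px"` or
#'   `"pursuit_latency_s"`).
#' @param k number of vincentiles.
#' @return object of class `vincentile_table`: a 3-d array
#'   subject x condition x bin of bin means, plus metadata.
#' @export
vincentile_table <- function(data, measure, k = 10) {
  stopifnot(all(c("subject", "condition", measure) %in% names(data)))
  data <- data[is.finite(data[[measure]]), ]
  subjects <- sort(unique(data$subject))
  conditions <- sort(unique(data$condition))
  arr <- array(NA_real_, dim = c(length(subjects), length(conditions), k),
               dimnames = list(subject = as.character(subjects),
                               condition = conditions, bin = seq_len(k)))
  for (s in seq_along(subjects)) {
    for (cnd in seq_along(conditions)) {
      v <- data[[measure]][data$subject == subjects[s] & data$condition == conditions[cnd]]
      arr[s, cnd, ] <- vincentilize(v, k = k,
                                    label = paste(subjects[s], conditions[cnd], sep = " / "))
    }
  }
  structure(list(values = arr, measure = measure, k = k,
                 subjects = subjects, conditions = conditions),
            class = "vincentile_table")
}

#' Per-vincentile condition contrast
#'
#' For each of the `k` vincentiles, runs a bootstrap paired t-test between two
#' conditions across subjects, then applies BH-FDR over the `k` p values.
#'
#' @param table a [vincentile_table()].
#' @param cond_a,cond_b condition labels to contrast (a minus b).
#' @param n_boot,alpha,q bootstrap samples, test alpha, FDR level.
#' @param seed optional seed.
#' @return object of class `contrast_result`: `t_per_bin`, `p_per_bin`,
#'   `d_per_bin`, `fdr_mask`, `significant` (fdr mask and p below alpha),
#'   `bin_means` (condition x bin grand means).
#' @export
vincentile_contrast <- function(table, cond_a, cond_b, n_boot = 5000,
                                alpha = 0.001, q = 0.05, seed = NULL) {
  stopifnot(inherits(table, "vincentile_table"),
            all(c(cond_a, cond_b) %in% table$conditions))
  k <- table$k
  t_v <- p_v <- d_v <- rep(NA_real_, k)
  for (bin in seq_len(k)) {
    av <- table$values[, cond_a, bin]
    bv <- table$values[, cond_b, bin]
    ok <- is.finite(av) & is.finite(bv)
    res <- bootstrap_paired_test(av[ok], bv[ok], n_boot = n_boot,
                                 seed = if (is.null(seed)) NULL else derive_seed(seed, bin))
    t_v[bin] <- res$t; p_v[bin] <- res$p; d_v[bin] <- res$d
  }
  mask <- fdr_correct(p_v, q = q)
  bin_means <- apply(table$values[, c(cond_a, cond_b), , drop = FALSE], c(2, 3),
                     mean, na.rm = TRUE)
  structure(list(measure = table$measure, cond_a = cond_a, cond_b = cond_b,
                 t_per_bin = t_v, p_per_bin = p_v, d_per_bin = d_v,
                 fdr_mask = mask, significant = mask & p_v <= alpha,
                 bin_means = bin_means, n_boot = n_boot, alpha = alpha, q = q),
            class = "contrast_result")
}

#' Sort epoch error by pursuit-latency vincentiles
#'
#' Bins epochs by the rank of their pursuit latency within subject and
#' condition, and returns the mean epoch error per latency vincentile — a
#' measure of association between the two performance measures. Epochs without
#' a valid latency are excluded and counted.
#'
#' @param data data.frame with `subject`, `condition`, `pursuit_latency_s`,
#'   `epoch_error_px` (and optionally `valid`).
#' @param k number of vincentiles.
#' @return list: `cells` data.frame (subject, condition, bin,
#'   mean_epoch_error_px, mean_latency_s), `bin_means` (condition x bin grand
#'   means of epoch error), `n_excluded`.
#' @export
cross_sort <- function(data, k = 10) {
  stopifnot(all(c("subject", "condition", "pursuit_latency_s", "epoch_error_px")
                %in% names(data)))
  ok <- is.finite(data$pursuit_latency_s) & is.finite(data$epoch_error_px)
  if ("valid" %in% names(data)) ok <- ok & data$valid
  n_excluded <- sum(!ok)
  data <- data[ok, ]
  cells <- list()
  for (s in unique(data$subject)) {
    for (cnd in unique(data$condition)) {
      d <- data[data$subject == s & data$condition == cnd, ]
      if (nrow(d) < k) next
      bin <- vincentile_assign(d$pursuit_latency_s, k = k)
      cells[[length(cells) + 1L]] <- data.frame(
        subject = s, condition = cnd, bin = seq_len(k),
        mean_epoch_error_px = as.numeric(tapply(d$epoch_error_px, bin, mean)),
        mean_latency_s = as.numeric(tapply(d$pursuit_latency_s, bin, mean)))
    }
  }
  cells <- do.call(rbind, cells)
  bin_means <- if (!is.null(cells)) {
    tapply(cells$mean_epoch_error_px, list(cells$condition, cells$bin), mean)
  } else NULL
  list(cells = cells, bin_means = bin_means, n_excluded = n_excluded)
}
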