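# Study configuration: one list collecting every stated design constant and
# analysis threshold, with the published values as defaults.

#' Study configuration
#'
#' Collects the design constants and analysis thresholds used throughout the
#' pipeline. Defaults are the study's values: 60 Hz behavior, 250 Hz EEG,
#' 1% / 5% peak-prominence thresholds, 80-300 ms valid-latency window,
#' sample-entropy m = 2 with r = 0.2 SD, 10 vincentiles, 5000 bootstrap
#' samples at alpha 0.001 with FDR q = 0.05, 1000 (time-frequency) and
#' 3000 (ERP) permutation iterations at cluster alpha 0.001.
#'
#' @param ... named overrides of any default field.
#' @return a validated list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    task = 1,
    # geometry / timing
    screen_width_px = 1920, screen_height_px = 1080, target_size_px = 32,
    behavior_rate_hz = 60, eeg_rate_hz = 250,
    velocity_durations_s = c(13.5, 12, 10.5),
    start_vector_s = 0.5, gap_px = 30,
    occlusion_visible_s = 2, occlusion_occluded_s = 2,
    # session structure
    n_reps_per_cell = 12, break_every = 10, break_duration_s = 30,
    fixation_min_s = 1.0, fixation_max_s = 2.0,
    # behavior metrics
    prominence_fraction_target = 0.01, prominence_fraction_pursuit = 0.05,
    latency_window_s = c(0.08, 0.30),
    entropy_m = 2, entropy_r_factor = 0.2,
    entropy_split_s = 0.5, entropy_horizon_s = 2.0,
    outlier_sd = 3,
    # statistics
    vincentile_k = 10, n_boot = 5000, boot_alpha = 0.001, fdr_q = 0.05,
    n_perm_tf = 1000, n_perm_erp = 3000, cluster_alpha = 0.001,
    erp_min_neighbors = 4,
    # EEG
    n_channels = 60, morlet_cycles = 5,
    tf_baseline_s = c(-0.75, 0),
    erp_window_s = c(-0.5, 0.75), erp_baseline_s = c(-0.5, 0),
    csd_m = 4, csd_lambda = 1e-5, csd_n_legendre = 50,
    dbscan_tail_fraction = 0.01, dbscan_eps_factor = 1.5, dbscan_min_pts = 5,
    # study scale
    n_subjects = 30,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = c("study_config", "list"))
}

#' @rdname study_config
#' @param cfg a config list to validate.
#' @export
validate_config <- function(cfg) {
  if (!cfg$task %in% 1:2) stop("config: task must be 1 or 2")
  stopifnot(cfg$behavior_rate_hz > 0, cfg$eeg_rate_hz > 0,
            length(cfg$velocity_durations_s) == 3,
            cfg$vincentile_k >= 2, cfg$n_boot >= 1,
            cfg$boot_alpha > 0, cfg$boot_alpha < 1,
            cfg$cluster_alpha > 0, cfg$cluster_alpha < 1,
            cfg$fdr_q > 0, cfg$fdr_q <= 1,
            length(cfg$latency_window_s) == 2,
            cfg$latency_window_s[1] < cfg$latency_window_s[2],
            cfg$entropy_m >= 1, cfg$entropy_r_factor > 0,
            cfg$n_subjects >= 2)
  invisible(cfg)
}

#' Read / write a study configuration (YAML or JSON)
#'
#' The serialization round-trips losslessly; format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#' @param cfg a `study_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(study_config, x)
}

#' Hash of a configuration (provenance)
#' @param cfg a `study_config`.
#' @return md5 string of the canonical JSON form.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}
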