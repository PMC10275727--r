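# Readers and writers for the behavioral CSV dialect, the internal EEG
# container, and the BrainVision triad; plus the pipeline driver.

BEHAVIOR_COLUMNS <- c("subject", "trial", "frame", "time_s", "x_px",
                      "target_y_px", "cursor_y_px", "segment_label", "occluded")

#' Write / read behavioral trial records (CSV)
#'
#' The dialect is one row per frame with columns `subject`, `trial`, `frame`,
#' `time_s`, `x_px`, `target_y_px`, `cursor_y_px`, `segment_label`,
#' `occluded`.
#'
#' @param records data.frame in the dialect above.
#' @param path CSV file path.
#' @export
write_behavior <- function(records, path) {
  missing_cols <- setdiff(BEHAVIOR_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records[, BEHAVIOR_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @return `read_behavior`: the records data.frame with an inferred
#'   `frame_rate` attribute (from the median inter-frame interval).
#' @export
read_behavior <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(BEHAVIOR_COLUMNS, names(d))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("time_s", "x_px", "target_y_px", "cursor_y_px")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1])
    }
    d[[col]] <- v
  }
  d$occluded <- as.logical(d$occluded)
  dt <- stats::median(diff(d$time_s[d$subject == d$subject[1] &
                                      d$trial == d$trial[1]]))
  attr(d, "frame_rate") <- round(1 / dt)
  d
}

#' Behavioral records of a synthetic study
#'
#' Flattens a [make_study()] result into the behavioral CSV dialect.
#' @param study a `synthetic_study`.
#' @return data.frame (one row per subject x trial x frame).
#' @export
study_to_behavior <- function(study) {
  rows <- list()
  for (s in seq_along(study$subjects)) {
    trials <- study$subjects[[s]]$trials
    for (k in seq_along(trials)) {
      tr <- trials[[k]]
      if (is.null(tr)) next
      d <- trajectory_to_df(tr$trajectory)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, trial = k, frame = d$frame, time_s = d$time_s,
        x_px = d$x_px, target_y_px = d$y_px, cursor_y_px = tr$cursor_y,
        segment_label = d$segment_label, occluded = d$occluded)
    }
  }
  do.call(rbind, rows)
}

# --- internal EEG container -------------------------------------------------
# Self-describing hierarchical binary file: magic line, a JSON header holding
# channels, montage, events and metadata, then the float64 data block
# (channels x samples, column-major by sample).

#' Write / read the internal EEG container
#'
#' @param eeg list with `data` (channels x samples), `sfreq`, `t0`, `montage`
#'   (data.frame) and `events` (data.frame), as produced by [simulate_eeg()].
#' @param path output file (convention: `.pmeeg`).
#' @export
write_eeg_container <- function(eeg, path) {
  header <- list(format = "pmeeg", version = 1L,
                 n_channels = nrow(eeg$data), n_samples = ncol(eeg$data),
                 sfreq = eeg$sfreq, t0 = eeg$t0 %||% 0,
                 montage = eeg$montage, events = eeg$events)
  hjson <- charToRaw(jsonlite::toJSON(header, digits = NA, auto_unbox = TRUE,
                                      dataframe = "columns", null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PMEEG1\n"), con)
  writeBin(length(hjson), con, size = 8, endian = "little")
  writeBin(hjson, con)
  writeBin(as.numeric(eeg$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_eeg_container
#' @export
read_eeg_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 7))
  if (magic != "PMEEG1\n") stop("unknown format: not a pmeeg container")
  hlen <- readBin(con, "integer", 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  n <- header$n_channels * header$n_samples
  data <- matrix(readBin(con, "numeric", n, size = 8, endian = "little"),
                 nrow = header$n_channels)
  montage <- if (!is.null(header$montage)) as.data.frame(header$montage) else NULL
  events <- if (!is.null(header$events) && length(header$events)) {
    as.data.frame(header$events)
  } else data.frame(time_s = numeric(0), condition = character(0))
  list(data = data, sfreq = header$sfreq, t0 = header$t0,
       montage = montage, events = events)
}

# --- BrainVision triad ------------------------------------------------------

#' Export / import the BrainVision format triad
#'
#' Writes `basename.vhdr` / `.vmrk` / `.eeg` (IEEE float32, multiplexed,
#' resolution 1 uV) for interoperability with standard EEG tooling, and reads
#' the same subset back.
#'
#' @param eeg list as for [write_eeg_container()].
#' @param basepath path without extension.
#' @export
write_brainvision <- function(eeg, basepath) {
  base <- basename(basepath)
  nch <- nrow(eeg$data)
  ch_names <- if (!is.null(eeg$montage)) eeg$montage$channel else sprintf("E%02d", seq_len(nch))
  vhdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / eeg$sfreq, scientific = FALSE)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), ch_names))
  writeLines(vhdr, paste0(basepath, ".vhdr"), useBytes = FALSE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000")
  ev <- eeg$events
  if (!is.null(ev) && nrow(ev)) {
    pos <- round((ev$time_s - (eeg$t0 %||% 0)) * eeg$sfreq) + 1L
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(ev)) + 1L,
                        ev$condition, pos))
  }
  writeLines(mk, paste0(basepath, ".vmrk"))
  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(eeg$data), con, size = 4, endian = "little")
  invisible(basepath)
}

#' @rdname write_brainvision
#' @param vhdr_path path to the `.vhdr` header file.
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, encoding = "UTF-8")
  field <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) stop("missing ", key, " in header")
    sub(paste0("^", key, "="), "", ln[1])
  }
  nch <- as.integer(field("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(field("SamplingInterval"))
  if (field("BinaryFormat") != "IEEE_FLOAT_32") stop("unsupported binary format")
  data_file <- file.path(dirname(vhdr_path), field("DataFile"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[[`, character(1), 1)
  raw_n <- file.size(data_file) / 4
  data <- matrix(readBin(data_file, "numeric", raw_n, size = 4, endian = "little"),
                 nrow = nch)
  # markers
  vmrk <- file.path(dirname(vhdr_path), field("MarkerFile"))
  events <- data.frame(time_s = numeric(0), condition = character(0))
  if (file.exists(vmrk)) {
    mlines <- grep("^Mk[0-9]+=Stimulus", readLines(vmrk), value = TRUE)
    if (length(mlines)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
      events <- data.frame(
        time_s = (vapply(parts, function(p) as.numeric(p[3]), 1) - 1) / sfreq,
        condition = vapply(parts, `[[`, character(1), 2))
    }
  }
  list(data = data, sfreq = sfreq, t0 = 0, channels = ch_names,
       montage = NULL, events = events)
}

#' Read an EEG file, dispatching on format
#'
#' `.vhdr` files are read as BrainVision; anything else as the internal
#' container.
#' @param path file path.
#' @export
read_eeg <- function(path) {
  if (grepl("\\.vhdr$", path)) read_brainvision(path) else read_eeg_container(path)
}

# --- pipeline ---------------------------------------------------------------

#' Run the analysis pipeline on a synthetic study
#'
#' Executes design -> synthesis -> behavioral metrics -> vincentile contrasts
#' -> time-frequency cluster test (when EEG is simulated), writing each
#' stage's outputs plus a provenance log (config hash, seed, package version,
#' stage status) under `out_dir`. Stage failures abort with the stage name;
#' outputs of completed stages are kept.
#'
#' @param config a [study_config()] (fields `n_subjects`, `task`, `seed`
#'   control the run).
#' @param out_dir output directory (created).
#' @param n_trials trials per subject (NULL = full plan).
#' @param include_eeg simulate EEG and run the time-frequency stage.
#' @param stages subset of `c("design", "synth", "behavior", "vincentiles",
#'   "tfr")` to run (later stages need earlier ones).
#' @return list of stage results (invisible), with provenance written to
#'   `out_dir/provenance.json`.
#' @export
run_pipeline <- function(config = study_config(), out_dir, n_trials = NULL,
                         include_eeg = FALSE,
                         stages = c("design", "synth", "behavior", "vincentiles")) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config_hash = config_hash(config), seed = config$seed,
              package_version = as.character(utils::packageVersion("pursuitmon")),
              stages = list())
  res <- list()
  run_stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    out <- tryCatch(expr, error = function(e) {
      log$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(log, file.path(out_dir, "provenance.json"),
                           digits = NA, auto_unbox = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log$stages[[name]] <<- list(status = "ok")
    out
  }

  res$design <- run_stage("design", {
    plan <- build_session_plan(task = config$task, seed = config$seed, config = config)
    write_session_plan(plan, file.path(out_dir, "session_plan.json"))
    plan
  })
  res$study <- run_stage("synth", {
    make_study(n_subjects = config$n_subjects, task = config$task,
               seed = config$seed, config = config, n_trials = n_trials,
               include_eeg = include_eeg)
  })
  res$metrics <- run_stage("behavior", {
    m <- res$study$metrics
    utils::write.csv(m[, c("subject", "trial", "condition", "epoch_error_px",
                           "pursuit_latency_s", "valid")],
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    m
  })
  res$vincentiles <- run_stage("vincentiles", {
    conds <- if (config$task == 1) c("constant", "random") else c("occluded", "visible")
    out <- list()
    for (measure in c("epoch_error_px", "pursuit_latency_s")) {
      d <- res$metrics[res$metrics$condition %in% conds, ]
      if (measure == "pursuit_latency_s") d <- d[d$valid, ]
      tab <- vincentile_table(d, measure, k = config$vincentile_k)
      ct <- vincentile_contrast(tab, conds[1], conds[2], n_boot = config$n_boot,
                                alpha = config$boot_alpha, q = config$fdr_q,
                                seed = derive_seed(config$seed, 77))
      out[[measure]] <- ct
    }
    jsonlite::write_json(
      lapply(out, function(ct) ct[c("measure", "cond_a", "cond_b", "t_per_bin",
                                    "p_per_bin", "d_per_bin", "fdr_mask")]),
      file.path(out_dir, "vincentile_contrasts.json"), digits = NA, auto_unbox = TRUE)
    out
  })
  jsonlite::write_json(log, file.path(out_dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(res)
}
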