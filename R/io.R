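# Recording I/O: BrainVision triplet (.vhdr / .vmrk / .eeg, IEEE float 32,
# multiplexed) plus a BIDS-style tab-separated events file carrying the
# sample-exact schedule (onset seconds, duration, trial_type, sample, run,
# trial) and a YAML sidecar with the paradigm fields.

#' Write a recording to disk
#'
#' Writes `<base>.vhdr`, `<base>.vmrk`, `<base>.eeg` (binary IEEE float 32,
#' multiplexed), `<base>_events.tsv` and `<base>_config.yaml`.
#'
#' @param rec An `eeg_recording`.
#' @param base Path base (a trailing `.vhdr` is stripped).
#' @return `base`, invisibly.
#' @export
write_recording <- function(rec, base) {
  base <- sub("\\.vhdr$", "", base)
  name <- basename(base)
  n_ch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", name),
    sprintf("MarkerFile=%s.vmrk", name),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%g", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(n_ch), rec$channel_labels))
  writeLines(hdr, paste0(base, ".vhdr"))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Common Infos]", "Codepage=UTF-8",
           sprintf("DataFile=%s.eeg", name), "[Marker Infos]",
           sprintf("Mk1=New Segment,,1,1,0"))
  if (!is.null(rec$schedule) && nrow(rec$schedule$events) > 0) {
    ev <- rec$schedule$events
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(ev)) + 1L, ev$type,
                          ev$onset_sample + 1L))
  }
  writeLines(mrk, paste0(base, ".vmrk"))
  con <- file(paste0(base, ".eeg"), "wb")
  writeBin(as.vector(rec$data), con, size = 4)
  close(con)
  write_events_tsv(rec, paste0(base, "_events.tsv"))
  cfg <- rec$schedule$config
  yaml::write_yaml(list(
    fs = rec$fs, eog_labels = rec$channel_labels[rec$eog_indices],
    n_runs = cfg$n_runs %||% NA, trials_per_run = cfg$trials_per_run %||% NA,
    non_emergency_duration = cfg$non_emergency_duration %||% NA,
    emergency_duration = cfg$emergency_duration %||% NA,
    inter_run_gap = cfg$inter_run_gap %||% NA,
    lead_in = cfg$lead_in %||% NA, lead_out = cfg$lead_out %||% NA),
    paste0(base, "_config.yaml"))
  invisible(base)
}

write_events_tsv <- function(rec, path) {
  if (is.null(rec$schedule) || nrow(rec$schedule$events) == 0) {
    utils::write.table(
      data.frame(onset = numeric(0), duration = numeric(0),
                 trial_type = character(0), sample = integer(0),
                 run = integer(0), trial = integer(0)),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  ev <- rec$schedule$events
  cfg <- rec$schedule$config
  dur <- c(non_emergency = cfg$non_emergency_duration %||% 0,
           emergency = cfg$emergency_duration %||% 0, keypress = 0)
  utils::write.table(
    data.frame(onset = ev$onset_sample / rec$fs,
               duration = unname(dur[ev$type]),
               trial_type = ev$type, sample = ev$onset_sample,
               run = ev$run, trial = ev$trial),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param base Path base or `.vhdr` path.
#' @return An `eeg_recording` (data quantised to float 32 by the format).
#' @export
read_recording <- function(base) {
  base <- sub("\\.vhdr$", "", base)
  hdr_path <- paste0(base, ".vhdr")
  if (!file.exists(hdr_path)) stopf("no header file at %s", hdr_path)
  hdr <- readLines(hdr_path)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(ln) == 0) stopf("header lacks %s", key)
    sub(paste0("^", key, "="), "", ln[1])
  }
  if (get1("BinaryFormat") != "IEEE_FLOAT_32" ||
      get1("DataOrientation") != "MULTIPLEXED")
    stopf("unsupported binary layout")
  n_ch <- as.integer(get1("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get1("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  if (length(labels) != n_ch) stopf("channel list length mismatch")
  eeg_path <- paste0(base, ".eeg")
  sz <- file.info(eeg_path)$size
  n_samp <- as.integer(sz / 4 / n_ch)
  con <- file(eeg_path, "rb")
  raw <- readBin(con, "numeric", n = n_ch * n_samp, size = 4)
  close(con)
  data <- matrix(raw, nrow = n_ch)
  cfg_path <- paste0(base, "_config.yaml")
  side <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  eog_labels <- side$eog_labels %||% grep("^EOG", labels, value = TRUE)
  ev_path <- paste0(base, "_events.tsv")
  schedule <- NULL
  if (file.exists(ev_path)) {
    tsv <- utils::read.delim(ev_path, stringsAsFactors = FALSE)
    cfg <- list(fs = fs,
                n_runs = side$n_runs, trials_per_run = side$trials_per_run,
                non_emergency_duration = side$non_emergency_duration,
                emergency_duration = side$emergency_duration,
                inter_run_gap = side$inter_run_gap,
                lead_in = side$lead_in, lead_out = side$lead_out,
                channel_labels = setdiff(labels, eog_labels),
                eog_labels = eog_labels)
    class(cfg) <- "paradigm_config"
    schedule <- structure(list(
      events = if (nrow(tsv) == 0)
        data.frame(onset_sample = integer(0), type = character(0),
                   run = integer(0), trial = integer(0))
      else data.frame(onset_sample = as.integer(tsv$sample),
                      type = tsv$trial_type, run = tsv$run, trial = tsv$trial),
      config = cfg, n_samples = n_samp), class = "event_schedule")
  }
  new_recording(data, fs, labels,
                eog_indices = match(eog_labels, labels), schedule)
}

#' Serialise a fitted HDCA model to versioned JSON
#' @param model An `hdca_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hdca_model <- function(model, path) {
  obj <- list(format = "emergeeg-hdca", version = 1,
              window_weights = model$window_weights,
              second_stage = model$second_stage,
              positive_class = model$positive_class,
              negative_class = model$negative_class,
              window_ms = model$window_ms, n_windows = model$n_windows,
              samples_per_window = model$samples_per_window,
              channels = model$channels, fs = model$fs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialised HDCA model
#' @param path JSON path from [write_hdca_model()].
#' @return An `hdca_model`.
#' @export
read_hdca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "emergeeg-hdca")) stopf("not an HDCA model file")
  model <- obj[setdiff(names(obj), c("format", "version"))]
  model$window_weights <- matrix(obj$window_weights,
                                 nrow = length(obj$channels),
                                 dimnames = list(obj$channels, NULL))
  class(model) <- "hdca_model"
  model
}
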