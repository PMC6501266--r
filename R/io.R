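#' Export epoched EEG to a long-format CSV with a JSON sidecar
#'
#' The CSV holds one row per (subject, trial, channel, time sample)
#' with columns `subject, trial, category, animacy, channel, time_ms,
#' value`; the sidecar (same path with `.json` appended) records the
#' subject order, channel order, time axis and sampling rate so the
#' array can be rebuilt exactly.
#'
#' @param d An [epoched_eeg()] dataset.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @seealso [read_eeg_csv()]
#' @export
write_eeg_csv <- function(d, path) {
  stopifnot(inherits(d, "epoched_eeg"))
  dims <- dim(d$data)
  long <- data.frame(
    subject = rep(d$subject_ids, times = prod(dims[2:4])),
    trial = rep(rep(seq_len(dims[2]), each = dims[1]), times = prod(dims[3:4])),
    channel = rep(rep(d$channel_names, each = prod(dims[1:2])),
                  times = dims[4]),
    time_ms = rep(d$times_ms, each = prod(dims[1:3])),
    value = as.vector(d$data),
    stringsAsFactors = FALSE
  )
  long$category <- as.vector(d$category_labels)[
    (long$trial - 1L) * dims[1] + match(long$subject, d$subject_ids)]
  long$animacy <- as.vector(d$animacy_labels)[
    (long$trial - 1L) * dims[1] + match(long$subject, d$subject_ids)]
  long <- long[, c("subject", "trial", "category", "animacy",
                   "channel", "time_ms", "value")]
  write.csv(long, path, row.names = FALSE)
  sidecar <- list(subject_ids = d$subject_ids,
                  channel_names = d$channel_names,
                  times_ms = d$times_ms,
                  sampling_rate_hz = d$sampling_rate_hz)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import epoched EEG from a long-format CSV
#'
#' Rebuilds the [epoched_eeg()] container written by [write_eeg_csv()].
#' The JSON sidecar is used when present to restore subject/channel
#' order and the sampling rate; otherwise order of appearance is used
#' and the rate is inferred from the time axis.
#'
#' @param path CSV path.
#' @return An [epoched_eeg()] dataset.
#' @export
read_eeg_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    subjects <- side$subject_ids
    channels <- side$channel_names
    times <- side$times_ms
    rate <- side$sampling_rate_hz
  } else {
    subjects <- unique(long$subject)
    channels <- unique(long$channel)
    times <- sort(unique(long$time_ms))
    rate <- 1000 / mean(diff(times))
  }
  n_s <- length(subjects); n_c <- length(channels); n_t <- length(times)
  n_trials <- max(long$trial)
  data <- array(NA_real_, dim = c(n_s, n_trials, n_c, n_t))
  si <- match(long$subject, subjects)
  ci <- match(long$channel, channels)
  ti <- match(long$time_ms, times)
  data[cbind(si, long$trial, ci, ti)] <- long$value
  first <- !duplicated(paste(si, long$trial))
  cat_lab <- matrix(NA_integer_, n_s, n_trials)
  ani_lab <- matrix(NA_real_, n_s, n_trials)
  cat_lab[cbind(si[first], long$trial[first])] <- long$category[first]
  ani_lab[cbind(si[first], long$trial[first])] <- long$animacy[first]
  epoched_eeg(data, subjects, cat_lab, ani_lab, channels, times, rate)
}

#' Serialise a cross-validation result
#'
#' Writes the per-subject fold table as CSV and the summary plus
#' scheme metadata as JSON.
#'
#' @param cv A `cv_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return The directory, invisibly.
#' @export
write_cv_result <- function(cv, dir, prefix = "cv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cv$folds, file.path(dir, paste0(prefix, "_folds.csv")),
            row.names = FALSE)
  meta <- list(scheme = cv$scheme, mode = cv$mode,
               test_unit = cv$test_unit, grid_preset = cv$grid_preset,
               biased = isTRUE(cv$biased), summary = cv$summary)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
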