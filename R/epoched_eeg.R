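#' Epoched EEG container
#'
#' Bundles a 4-dimensional array of epoched EEG (subject x trial x
#' channel x time sample) with per-trial category and animacy labels and
#' the recording geometry. All subjects must hold the same number of
#' trials; animacy is +1 for animate and -1 for inanimate trials.
#'
#' @param data Numeric 4-d array with dimensions
#'   `(n_subjects, n_trials, n_channels, n_times)`.
#' @param subject_ids Character vector of subject identifiers.
#' @param category_labels Integer matrix `(n_subjects, n_trials)` with
#'   values in `1..n_categories`.
#' @param animacy_labels Matrix `(n_subjects, n_trials)` with values in
#'   `{-1, +1}` (+1 = animate).
#' @param channel_names Character vector of montage labels.
#' @param times_ms Numeric vector of per-sample time stamps in ms
#'   relative to stimulus onset.
#' @param sampling_rate_hz Sampling rate in Hz.
#'
#' @return An object of class `epoched_eeg`.
#' @seealso [validate_dataset()], [zscore_trials()], [flatten()]
#' @export
epoched_eeg <- function(data, subject_ids, category_labels, animacy_labels,
                        channel_names, times_ms, sampling_rate_hz) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  d <- structure(
    list(
      data = data,
      subject_ids = as.character(subject_ids),
      category_labels = category_labels,
      animacy_labels = animacy_labels,
      channel_names = as.character(channel_names),
      times_ms = as.numeric(times_ms),
      sampling_rate_hz = as.numeric(sampling_rate_hz)
    ),
    class = "epoched_eeg"
  )
  dims <- dim(data)
  if (length(subject_ids) != dims[1L])
    stop("subject_ids length does not match data")
  if (!all(dim(category_labels) == dims[1:2]))
    stop("category_labels shape does not match data")
  if (!all(dim(animacy_labels) == dims[1:2]))
    stop("animacy_labels shape does not match data")
  if (length(channel_names) != dims[3L])
    stop("channel_names length does not match data")
  if (length(times_ms) != dims[4L])
    stop("times_ms length does not match data")
  d
}

#' @export
print.epoched_eeg <- function(x, ...) {
  dims <- dim(x$data)
  cat(sprintf(
    "<epoched_eeg> %d subjects x %d trials x %d channels x %d samples\n",
    dims[1], dims[2], dims[3], dims[4]))
  cat(sprintf("  time: [%g, %g] ms at %g Hz\n",
              min(x$times_ms), max(x$times_ms), x$sampling_rate_hz))
  cat(sprintf("  animate trials per subject: %d of %d\n",
              sum(x$animacy_labels[1, ] == 1), dims[2]))
  invisible(x)
}

#' Validate an epoched EEG dataset
#'
#' Checks the container invariants: label extents match the data, every
#' category carries a single animacy label, and the time axis is
#' strictly increasing and uniformly spaced at `1000 / sampling_rate_hz`
#' ms. Returns a report instead of raising, so callers can inspect all
#' failures at once.
#'
#' @param d An [epoched_eeg()] object.
#' @return A list of class `validation_report` with elements `passed`
#'   (logical scalar) and `checks`, a data frame with one row per check
#'   (`check`, `passed`, `detail`).
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "epoched_eeg"))
  dims <- dim(d$data)
  checks <- list()
  add <- function(check, passed, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, passed = passed, detail = detail,
      stringsAsFactors = FALSE)
  }

  add("label_extent",
      all(dim(d$category_labels) == dims[1:2]) &&
        all(dim(d$animacy_labels) == dims[1:2]),
      sprintf("data is %d x %d trials", dims[1], dims[2]))

  add("animacy_values", all(d$animacy_labels %in% c(-1, 1)),
      "animacy labels must be -1 or +1")

  # each category must be wholly animate or wholly inanimate
  per_cat <- tapply(as.vector(d$animacy_labels),
                    as.vector(d$category_labels),
                    function(a) length(unique(a)))
  mixed <- names(per_cat)[per_cat > 1L]
  add("category_animacy_consistent", length(mixed) == 0L,
      if (length(mixed)) paste("mixed animacy in category:",
                               paste(mixed, collapse = ", ")) else "")

  dt <- diff(d$times_ms)
  expected_dt <- 1000 / d$sampling_rate_hz
  uniform <- length(dt) > 0L && all(dt > 0) &&
    max(abs(dt - expected_dt)) < 1e-9
  add("time_axis_uniform", uniform,
      if (!uniform) "time axis not uniform" else
        sprintf("step %g ms", expected_dt))

  checks <- do.call(rbind, checks)
  structure(list(passed = all(checks$passed), checks = checks),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s\n",
              if (x$passed) "all checks passed" else "FAILED"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' Z-score every trial across channels and time samples
#'
#' Normalises each (subject, trial) channel-by-time block to mean 0 and
#' standard deviation 1 over all of its channel x time entries. The
#' population convention (divide by n) is used, so a z-scored block has
#' exactly unit population standard deviation and the operation is
#' idempotent. Labels and metadata are unchanged.
#'
#' @param d An [epoched_eeg()] object.
#' @return A new `epoched_eeg` with normalised data.
#' @export
zscore_trials <- function(d) {
  stopifnot(inherits(d, "epoched_eeg"))
  dims <- dim(d$data)
  n_feat <- dims[3] * dims[4]
  # columns of `m` are (subject, trial) blocks in channel-major order
  m <- matrix(aperm(d$data, c(3, 4, 2, 1)), nrow = n_feat)
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu, "-")
  sd_pop <- sqrt(colMeans(m^2))
  if (any(sd_pop == 0)) {
    bad <- which(sd_pop == 0)[1L]
    s <- (bad - 1L) %/% dims[2] + 1L
    tr <- (bad - 1L) %% dims[2] + 1L
    stop(sprintf("constant trial: subject %s, trial %d",
                 d$subject_ids[s], tr))
  }
  m <- sweep(m, 2L, sd_pop, "/")
  d$data <- aperm(array(m, dim = dims[c(3, 4, 2, 1)]), c(4, 3, 1, 2))
  d
}

#' Flatten epoched EEG into a feature matrix
#'
#' Turns each trial's channel x time block into one feature row. The
#' feature ordering is channel-major: feature `j` maps to channel
#' `(j - 1) %% n_channels + 1` and time sample
#' `(j - 1) %/% n_channels + 1`. Rows are ordered subject-major
#' (all trials of the first requested subject, then the next).
#'
#' @param d An [epoched_eeg()] object.
#' @param subjects Subject identifiers to include (default all).
#' @return A list of class `feature_matrix` with elements `x` (rows =
#'   observations), `labels` (animacy, -1/+1), `groups` (subject id per
#'   row), `trial` (within-subject trial index), `category` (category
#'   label per row), `channel_names`, `times_ms`.
#' @export
flatten <- function(d, subjects = d$subject_ids) {
  stopifnot(inherits(d, "epoched_eeg"))
  unknown <- setdiff(subjects, d$subject_ids)
  if (length(unknown))
    stop("unknown subject id: ", paste(unknown, collapse = ", "))
  idx <- match(subjects, d$subject_ids)
  dims <- dim(d$data)
  n_feat <- dims[3] * dims[4]
  blocks <- lapply(idx, function(s) {
    t(matrix(aperm(d$data[s, , , , drop = FALSE][1, , , ],
                   c(2, 3, 1)), nrow = n_feat))
  })
  x <- do.call(rbind, blocks)
  structure(
    list(
      x = x,
      labels = as.vector(t(d$animacy_labels[idx, , drop = FALSE])),
      groups = rep(d$subject_ids[idx], each = dims[2]),
      trial = rep(seq_len(dims[2]), times = length(idx)),
      category = as.vector(t(d$category_labels[idx, , drop = FALSE])),
      channel_names = d$channel_names,
      times_ms = d$times_ms
    ),
    class = "feature_matrix"
  )
}

#' Rebuild an epoched EEG object from a flattened feature matrix
#'
#' Inverse of [flatten()]: restores the subject x trial x channel x time
#' array for the subjects present in the feature matrix.
#'
#' @param fm A `feature_matrix` produced by [flatten()].
#' @param sampling_rate_hz Sampling rate of the reconstructed container;
#'   defaults to the rate implied by `fm$times_ms`.
#' @return An [epoched_eeg()] object.
#' @export
unflatten <- function(fm, sampling_rate_hz = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$groups)
  n_ch <- length(fm$channel_names)
  n_t <- length(fm$times_ms)
  n_trials <- length(unique(fm$trial))
  data <- array(NA_real_, dim = c(length(subjects), n_trials, n_ch, n_t))
  cat_lab <- matrix(NA_integer_, length(subjects), n_trials)
  ani_lab <- matrix(NA_real_, length(subjects), n_trials)
  for (si in seq_along(subjects)) {
    rows <- which(fm$groups == subjects[si])
    rows <- rows[order(fm$trial[rows])]
    for (k in seq_along(rows)) {
      data[si, k, , ] <- matrix(fm$x[rows[k], ], n_ch, n_t)
    }
    cat_lab[si, ] <- fm$category[rows]
    ani_lab[si, ] <- fm$labels[rows]
  }
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- 1000 / mean(diff(fm$times_ms))
  }
  epoched_eeg(data, subjects, cat_lab, ani_lab,
              fm$channel_names, fm$times_ms, sampling_rate_hz)
}

#' Map feature indices to (channel, time) pairs
#'
#' @param fm A `feature_matrix` (or anything with `channel_names` and
#'   `times_ms` fields).
#' @return Data frame with one row per feature: `feature`, `channel`,
#'   `time_ms`.
#' @export
feature_grid <- function(fm) {
  n_ch <- length(fm$channel_names)
  n_t <- length(fm$times_ms)
  data.frame(
    feature = seq_len(n_ch * n_t),
    channel = rep(fm$channel_names, times = n_t),
    time_ms = rep(fm$times_ms, each = n_ch),
    stringsAsFactors = FALSE
  )
}
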