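#' Subject-level and grand-average ERPs per animacy class
#'
#' Averages each subject's trials within the animate and inanimate
#' classes into channels x time waveforms, then averages the subject
#' means (equally weighted, regardless of trial counts) into grand
#' averages with per-sample standard errors across subjects.
#'
#' @param d An [epoched_eeg()] dataset; every subject must hold at
#'   least one trial of each class.
#' @return A list of class `erp_set`: `subject_means` (array
#'   `subject x class x channel x time`, classes ordered animate,
#'   inanimate), `grand_animate`, `grand_inanimate`, `grand_sem_*`
#'   (channels x time matrices), `channel_names`, `times_ms`,
#'   `subject_ids`.
#' @export
compute_erps <- function(d) {
  stopifnot(inherits(d, "epoched_eeg"))
  dims <- dim(d$data)
  n_s <- dims[1]
  sub_means <- array(NA_real_, dim = c(n_s, 2, dims[3], dims[4]),
                     dimnames = list(d$subject_ids,
                                     c("animate", "inanimate"),
                                     d$channel_names, d$times_ms))
  for (s in seq_len(n_s)) {
    for (cl in 1:2) {
      lab <- c(1, -1)[cl]
      rows <- which(d$animacy_labels[s, ] == lab)
      if (length(rows) == 0L)
        stop(sprintf("subject %s has no %s trials", d$subject_ids[s],
                     c("animate", "inanimate")[cl]))
      block <- d$data[s, rows, , , drop = FALSE]
      dim(block) <- c(length(rows), dims[3], dims[4])
      sub_means[s, cl, , ] <- colMeans(block)
    }
  }
  grand <- apply(sub_means, c(2, 3, 4), mean)
  sem <- apply(sub_means, c(2, 3, 4), sd) / sqrt(n_s)
  structure(list(
    subject_means = sub_means,
    grand_animate = grand[1, , ],
    grand_inanimate = grand[2, , ],
    grand_sem_animate = sem[1, , ],
    grand_sem_inanimate = sem[2, , ],
    channel_names = d$channel_names,
    times_ms = d$times_ms,
    subject_ids = d$subject_ids
  ), class = "erp_set")
}

#' Animate minus inanimate ERP difference map
#'
#' Grand-average animate ERP minus grand-average inanimate ERP, so a
#' positive value means a stronger response to animate stimuli.
#'
#' @param e An `erp_set` from [compute_erps()].
#' @return A [scalp_time_map()] of kind `"erp_difference"`.
#' @export
erp_difference_map <- function(e) {
  stopifnot(inherits(e, "erp_set"))
  scalp_time_map(e$grand_animate - e$grand_inanimate,
                 e$channel_names, e$times_ms, kind = "erp_difference")
}

#' Bonferroni-corrected paired t-test map
#'
#' Paired t statistics across subjects of the animate minus inanimate
#' subject-mean difference, per map cell. Two correction scopes are
#' offered: `"time_by_channel"` (default) tests every channel x time
#' cell at `alpha / (n_times * n_channels)`; `"time_only"` first
#' averages the subject means over a channel selection (default the
#' occipital/parietal set O1, O2, Oz, PO3, PO4 where present) and tests
#' the resulting single trace at `alpha / n_times`.
#'
#' Cells with zero variance across subjects get `t = +/-Inf` and are
#' significant iff the mean difference is nonzero; a cell that is
#' identically zero gets `t = 0`.
#'
#' @param e An `erp_set` (at least 3 subjects).
#' @param alpha Familywise significance level before correction.
#' @param correction_scope `"time_by_channel"` or `"time_only"`.
#' @param channels Channel selection for `"time_only"`.
#' @return A list of class `ttest_map`: `t_map` (a [scalp_time_map()]
#'   of kind `"t_statistic"`; one row for `"time_only"`), `p_values`,
#'   `significant` (logical matrix), `threshold` (the corrected
#'   per-test alpha), `n_tests`, `df`.
#' @export
paired_ttest_map <- function(e, alpha = 0.05,
                             correction_scope = c("time_by_channel",
                                                  "time_only"),
                             channels = c("O1", "O2", "Oz", "PO3", "PO4")) {
  stopifnot(inherits(e, "erp_set"))
  correction_scope <- match.arg(correction_scope)
  n_s <- length(e$subject_ids)
  if (n_s < 3L) stop("paired t-test map needs at least 3 subjects")

  diffs <- e$subject_means[, 1, , , drop = FALSE] -
    e$subject_means[, 2, , , drop = FALSE]   # subject x 1 x ch x time
  dim(diffs) <- dim(e$subject_means)[c(1, 3, 4)]

  if (correction_scope == "time_only") {
    sel <- intersect(channels, e$channel_names)
    if (length(sel) == 0L) stop("no requested channels in the montage")
    ci <- match(sel, e$channel_names)
    diffs <- apply(diffs[, ci, , drop = FALSE], c(1, 3), mean)
    dim(diffs) <- c(n_s, 1, length(e$times_ms))
    ch_names <- paste(sel, collapse = "+")
    n_tests <- length(e$times_ms)
  } else {
    ch_names <- e$channel_names
    n_tests <- length(e$channel_names) * length(e$times_ms)
  }

  mean_d <- apply(diffs, c(2, 3), mean)
  sd_d <- apply(diffs, c(2, 3), sd)
  t_stat <- mean_d / (sd_d / sqrt(n_s))
  # zero-variance cells: +/-Inf when the mean is nonzero, 0 otherwise
  degen <- sd_d == 0
  t_stat[degen] <- sign(mean_d[degen]) * Inf
  t_stat[degen & mean_d == 0] <- 0

  p <- 2 * pt(-abs(t_stat), df = n_s - 1)
  threshold <- alpha / n_tests
  structure(list(
    t_map = scalp_time_map(t_stat, ch_names, e$times_ms,
                           kind = "t_statistic"),
    p_values = p,
    significant = p < threshold,
    threshold = threshold,
    n_tests = n_tests,
    df = n_s - 1,
    correction_scope = correction_scope
  ), class = "ttest_map")
}

#' @export
print.ttest_map <- function(x, ...) {
  cat(sprintf(
    "<ttest_map> %s scope, df = %d, per-test alpha = %.3g (%d tests)\n",
    x$correction_scope, x$df, x$threshold, x$n_tests))
  cat(sprintf("  %d of %d cells significant\n",
              sum(x$significant), length(x$significant)))
  invisible(x)
}
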