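#' Average trials into category pseudotrials
#'
#' Collapses each subject's trials to one pseudotrial per category by
#' sample-wise arithmetic averaging, the standard denoising step before
#' training a classifier on category-level responses. The result reuses
#' the [epoched_eeg()] container with one trial per category (ordered by
#' category label) and records how many trials entered each average.
#'
#' Averaging is linear, so it commutes with any per-sample linear map
#' applied to the underlying trials; if the trials carry iid noise of sd
#' `sigma`, the pseudotrial noise sd is `sigma / sqrt(n_trials)`.
#'
#' @param d An [epoched_eeg()] dataset.
#' @return An `epoched_eeg` that is also of class `pseudotrial_set`,
#'   with `n_averaged` (subjects x categories matrix of trial counts).
#' @export
average_categories <- function(d) {
  stopifnot(inherits(d, "epoched_eeg"))
  dims <- dim(d$data)
  cats <- sort(unique(as.vector(d$category_labels)))
  n_cat <- length(cats)
  out <- array(0, dim = c(dims[1], n_cat, dims[3], dims[4]))
  n_averaged <- matrix(0L, dims[1], n_cat,
                       dimnames = list(d$subject_ids, cats))
  cat_lab <- matrix(rep(cats, each = dims[1]), dims[1], n_cat)
  ani_lab <- matrix(NA_real_, dims[1], n_cat)

  for (s in seq_len(dims[1])) {
    for (ci in seq_len(n_cat)) {
      rows <- which(d$category_labels[s, ] == cats[ci])
      if (length(rows) == 0L)
        stop(sprintf("no trials for subject %s, category %s",
                     d$subject_ids[s], cats[ci]))
      n_averaged[s, ci] <- length(rows)
      block <- d$data[s, rows, , , drop = FALSE]
      dim(block) <- c(length(rows), dims[3], dims[4])
      out[s, ci, , ] <- colMeans(block)
      ani <- unique(d$animacy_labels[s, rows])
      if (length(ani) != 1L)
        stop(sprintf("category %s has mixed animacy labels", cats[ci]))
      ani_lab[s, ci] <- ani
    }
  }

  ps <- epoched_eeg(out, d$subject_ids, cat_lab, ani_lab,
                    d$channel_names, d$times_ms, d$sampling_rate_hz)
  ps$n_averaged <- n_averaged
  class(ps) <- c("pseudotrial_set", class(ps))
  ps
}
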