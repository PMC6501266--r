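#' NPAIRS split-half configuration
#'
#' @param n_splits Number of random splits `S` (default 100).
#' @param partition_size Subjects per partition (default 7, so that two
#'   disjoint partitions of a 15-subject dataset leave one subject out
#'   per split).
#' @param rng_seed Integer seed for the split draws.
#' @return A list of class `npairs_config`.
#' @export
npairs_config <- function(n_splits = 100, partition_size = 7,
                          rng_seed = 1L) {
  if (n_splits < 2) stop("n_splits must be at least 2")
  if (partition_size < 1) stop("partition_size must be positive")
  structure(list(n_splits = as.integer(n_splits),
                 partition_size = as.integer(partition_size),
                 rng_seed = as.integer(rng_seed)),
            class = "npairs_config")
}

#' Draw NPAIRS split-half partitions
#'
#' Each split consists of two disjoint subject sets of
#' `partition_size`, drawn without replacement; any remaining subjects
#' are left out of that split.
#'
#' @param subject_ids Subject identifiers.
#' @param cfg An [npairs_config()].
#' @return List of `n_splits` elements, each a list with `partition1`,
#'   `partition2`, `left_out`.
#' @export
make_splits <- function(subject_ids, cfg = npairs_config()) {
  n <- length(subject_ids)
  k <- cfg$partition_size
  if (2L * k > n)
    stop("partition constraint violated: 2 * partition_size exceeds ",
         "the subject count")
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed))
  set.seed(cfg$rng_seed)
  lapply(seq_len(cfg$n_splits), function(i) {
    perm <- sample(subject_ids)
    list(partition1 = perm[seq_len(k)],
         partition2 = perm[k + seq_len(k)],
         left_out = perm[-seq_len(2L * k)])
  })
}

#' NPAIRS effect-size scaling of a map
#'
#' Scales a full-data map into an effect size by split-half resampling:
#' for each of `S` splits, the map-producing procedure is run on two
#' disjoint subject partitions and the partition maps are differenced;
#' the resampling standard deviation is the square root of the grand
#' mean (over splits and all map elements) of the squared differences,
#' and the effect map is the full-data map divided elementwise by it.
#'
#' @param d An [epoched_eeg()] dataset.
#' @param map_fn Procedure `function(d, subjects)` returning a
#'   [scalp_time_map()] for that subject subset. Must be deterministic
#'   given the subset.
#' @param cfg An [npairs_config()].
#' @return A list of class `effect_size_result`: `full_map`, `sigma`,
#'   `effect_map`, `splits` (the subject assignments), `config`.
#' @export
npairs_effect_size <- function(d, map_fn, cfg = npairs_config()) {
  splits <- make_splits(d$subject_ids, cfg)
  sq_sum <- 0
  n_elem <- NULL
  for (sp in splits) {
    m1 <- map_fn(d, sp$partition1)
    m2 <- map_fn(d, sp$partition2)
    dif <- m1$values - m2$values
    if (is.null(n_elem)) n_elem <- length(dif)
    sq_sum <- sq_sum + sum(dif^2)
  }
  sigma <- sqrt(sq_sum / (cfg$n_splits * n_elem))
  if (sigma == 0)
    stop("degenerate resampling: identical partition maps")
  full_map <- map_fn(d, d$subject_ids)
  effect <- scalp_time_map(full_map$values / sigma,
                           full_map$channel_names, full_map$times_ms,
                           kind = "effect_size")
  structure(list(full_map = full_map, sigma = sigma,
                 effect_map = effect, splits = splits, config = cfg),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf(
    "<effect_size_result> %s map, sigma = %.6g over %d splits\n",
    x$full_map$kind, x$sigma, x$config$n_splits))
  cat(sprintf("  effect size range [%.4g, %.4g]\n",
              min(x$effect_map$values), max(x$effect_map$values)))
  invisible(x)
}

#' Map procedures for NPAIRS
#'
#' Ready-made `map_fn` arguments for [npairs_effect_size()]:
#' `erp_difference_mapper()` computes the grand-average animate minus
#' inanimate ERP difference of a subject subset;
#' `sensitivity_mapper()` trains an RBF-SVM on the subset at fixed
#' hyperparameters (the transferred or validation-mean parameters of a
#' prior cross-validation run; they are inputs here, never re-optimised
#' per split) and returns its mean-square sensitivity map.
#'
#' @param hp Fixed [hyper_params()] used for every subset fit.
#' @param mode Training unit for the subset classifier.
#' @param zscore_order Normalisation order for pseudotrial units.
#' @param aggregation Sensitivity aggregation, see [sensitivity_map()].
#' @return A function `(d, subjects) -> scalp_time_map`.
#' @export
sensitivity_mapper <- function(hp, mode = c("pseudotrial", "single_trial"),
                               zscore_order = "average_then_zscore",
                               aggregation = "mean_square") {
  mode <- match.arg(mode)
  function(d, subjects) {
    sub <- subset_subjects(d, subjects)
    units <- .prepare_units(sub, mode, zscore_order)
    m <- svm_fit(units, hp)
    sensitivity_map(m, aggregation = aggregation)
  }
}

#' @rdname sensitivity_mapper
#' @export
erp_difference_mapper <- function() {
  function(d, subjects) {
    erp_difference_map(compute_erps(subset_subjects(d, subjects)))
  }
}

#' Restrict a dataset to a subject subset
#'
#' @param d An [epoched_eeg()] dataset.
#' @param subjects Subject identifiers to keep.
#' @return An `epoched_eeg` with only those subjects, in the order of
#'   `d$subject_ids`.
#' @export
subset_subjects <- function(d, subjects) {
  idx <- sort(match(subjects, d$subject_ids))
  if (anyNA(idx)) stop("unknown subject id")
  epoched_eeg(d$data[idx, , , , drop = FALSE],
              d$subject_ids[idx],
              d$category_labels[idx, , drop = FALSE],
              d$animacy_labels[idx, , drop = FALSE],
              d$channel_names, d$times_ms, d$sampling_rate_hz)
}
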