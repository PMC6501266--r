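#' Permutation test of decoding accuracy
#'
#' Shuffles the true labels against the fixed predictions `n_perm`
#' times and compares the permuted accuracies with the observed one.
#' The p-value uses the add-one convention
#' `p = (1 + #{permuted accuracy >= observed}) / (n_perm + 1)`, so it
#' is never exactly zero.
#'
#' @param true_labels Vector of -1/+1 labels (both classes present).
#' @param predicted_labels Vector of predictions, same length.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return The permutation p-value.
#' @export
permutation_test <- function(true_labels, predicted_labels,
                             n_perm = 1000, seed = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (length(unique(true_labels)) < 2L)
    stop("true labels contain a single class")
  if (!is.null(seed)) {
    old_seed <- .save_rng_state()
    on.exit(.restore_rng_state(old_seed))
    set.seed(seed)
  }
  observed <- mean(true_labels == predicted_labels)
  n_ge <- 0L
  for (i in seq_len(n_perm)) {
    perm_acc <- mean(sample(true_labels) == predicted_labels)
    if (perm_acc >= observed) n_ge <- n_ge + 1L
  }
  (1 + n_ge) / (n_perm + 1)
}

#' Standard error of cross-validated accuracies with dependence
#' correction
#'
#' Cross-validation folds share training data, so fold accuracies are
#' positively correlated and the naive `sd / sqrt(K)` standard error is
#' too small. The correction inflates the variance by the test/train
#' size ratio: `SEM = sd * sqrt(1 / K + n_test / n_train)`. The naive
#' SEM is reported alongside.
#'
#' @param per_subject_accuracies Fold accuracies (at least 2).
#' @param n_train Training-set size per fold (observations).
#' @param n_test Test-set size per fold.
#' @return List with `corrected`, `naive`, and `rho` (the
#'   `n_test / n_train` ratio used).
#' @export
corrected_sem <- function(per_subject_accuracies, n_train, n_test) {
  k <- length(per_subject_accuracies)
  if (k < 2L) stop("need at least 2 folds")
  s <- sd(per_subject_accuracies)
  rho <- n_test / n_train
  list(corrected = s * sqrt(1 / k + rho),
       naive = s / sqrt(k),
       rho = rho)
}

#' Paired comparison of two cross-validation results
#'
#' Paired t-test across the per-subject accuracy pairs of two
#' `cv_result` objects over the same subjects.
#'
#' @param cv_a,cv_b `cv_result` objects with identical subject sets.
#' @return List of class `classifier_comparison`: `t`, `p`, `df`,
#'   `mean_difference` (a minus b), `conf_int` (95%), `degenerate`
#'   (TRUE when all pairwise differences are identical, in which case
#'   `t`/`p` are NA unless the common difference is zero).
#' @export
compare_classifiers <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  if (!identical(sort(cv_a$folds$subject), sort(cv_b$folds$subject)))
    stop("subject mismatch between the two results")
  a <- cv_a$folds$accuracy[order(cv_a$folds$subject)]
  b <- cv_b$folds$accuracy[order(cv_b$folds$subject)]
  dif <- a - b
  k <- length(dif)
  if (sd(dif) == 0) {
    res <- list(t = if (all(dif == 0)) 0 else NA_real_,
                p = if (all(dif == 0)) 1 else NA_real_,
                df = k - 1, mean_difference = mean(dif),
                conf_int = c(mean(dif), mean(dif)),
                degenerate = TRUE)
  } else {
    tt <- t.test(a, b, paired = TRUE)
    res <- list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter),
                mean_difference = unname(tt$estimate),
                conf_int = as.numeric(tt$conf.int),
                degenerate = FALSE)
  }
  class(res) <- "classifier_comparison"
  res
}

#' @export
print.classifier_comparison <- function(x, ...) {
  if (x$degenerate)
    cat("<classifier_comparison> degenerate: constant accuracy differences\n")
  cat(sprintf(
    "<classifier_comparison> mean diff %.4f, t(%d) = %s, p = %s\n",
    x$mean_difference, x$df,
    format(x$t, digits = 4), format(x$p, digits = 4)))
  invisible(x)
}
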