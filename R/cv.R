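# Leave-one-subject-out cross-validation schemes for the animacy
# decoders. All schemes share the same machinery: squared feature
# distances are computed once over every unit, kernels per gamma are
# exponentials of subsets, and each fold is a C-SVC fit on a
# precomputed kernel block.

# squared Euclidean distance matrix (BLAS-backed)
.sqdist <- function(X, Y = NULL) {
  sqx <- rowSums(X^2)
  if (is.null(Y)) {
    D <- tcrossprod(X)
    D <- sqx - 2 * D
    D <- t(D) + sqx
  } else {
    D <- tcrossprod(X, Y)
    D <- sqx - 2 * D
    D <- sweep(D, 2L, rowSums(Y^2), "+")
  }
  D[D < 0] <- 0
  D
}

# Classification units entering a classifier: single trials or category
# pseudotrials, z-scored per unit. For pseudotrials the default order
# averages raw trials first and z-scores the averages; the alternative
# z-scores trials before averaging.
.prepare_units <- function(d, unit, zscore_order = "average_then_zscore") {
  unit <- match.arg(unit, c("single_trial", "pseudotrial"))
  if (unit == "single_trial") {
    flatten(zscore_trials(d))
  } else if (zscore_order == "average_then_zscore") {
    flatten(zscore_trials(average_categories(d)))
  } else {
    flatten(average_categories(zscore_trials(d)))
  }
}

.eval_fold <- function(Ktr, ytr, Kcross, yte, c) {
  fit <- fit_kernel_matrix(Ktr, ytr, c)
  dv <- as.vector(Kcross %*% fit$alphas) + fit$b
  pred <- ifelse(dv > 0, 1, -1)
  list(accuracy = mean(pred == yte), pred = pred)
}

.new_cv_result <- function(folds, scheme, mode, test_unit, grid,
                           n_train, n_test, extra = list()) {
  acc <- folds$accuracy
  naive <- sd(acc) / sqrt(length(acc))
  corrected <- corrected_sem(acc, n_train = n_train, n_test = n_test)
  structure(
    c(list(
      folds = folds,
      summary = list(mean_accuracy = mean(acc),
                     corrected_sem = corrected$corrected,
                     naive_sem = naive),
      scheme = scheme, mode = mode, test_unit = test_unit,
      grid_preset = grid$preset
    ), extra),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s CV, %s classifier, %s test units\n",
              x$scheme, x$mode, x$test_unit))
  if (isTRUE(x$biased))
    cat("  NOTE: parameter selection used the test subject (optimistically biased)\n")
  cat(sprintf("  mean accuracy %.4f (corrected SEM %.4f, naive SEM %.4f) over %d subjects\n",
              x$summary$mean_accuracy, x$summary$corrected_sem,
              x$summary$naive_sem, nrow(x$folds)))
  print(x$folds, row.names = FALSE, digits = 4)
  invisible(x)
}

# select the best grid combination: highest score, ties broken by the
# (c, gamma)-ascending combination order
.select_combo <- function(combos, scores) {
  combos[which.max(scores), ]
}

.snap_to_grid <- function(value, grid_values, log_scale = FALSE) {
  if (log_scale) {
    grid_values[which.min(abs(log(grid_values) - log(value)))]
  } else {
    grid_values[which.min(abs(grid_values - value))]
  }
}

#' Nested leave-one-subject-out cross-validation
#'
#' Outer loop: each subject is held out for testing exactly once.
#' Inner loop: a second leave-one-subject-out over the remaining
#' training subjects selects the `(c, gamma)` pair with the highest
#' mean inner validation accuracy across the full grid (ties go to the
#' smallest `c`, then the smallest `gamma`). The model is then refit on
#' all training subjects at the selected pair and scored on the held-out
#' subject's test units.
#'
#' @param d An [epoched_eeg()] dataset (raw; normalisation is applied
#'   internally to whichever unit enters the classifier).
#' @param grid A [hyper_grid()].
#' @param mode Training unit: `"pseudotrial"` (category averages) or
#'   `"single_trial"`.
#' @param test_unit Unit scored on the held-out subject.
#' @param zscore_order For pseudotrial units, whether averaging precedes
#'   z-scoring (default) or follows it.
#' @param n_perm If positive, a per-subject permutation test of the
#'   held-out accuracy with this many label permutations.
#' @param perm_seed Seed for the permutation test.
#' @return A `cv_result`: per-subject fold table (`subject`,
#'   `accuracy`, `c`, `gamma`, `n_test`, `p_perm`), summary with mean
#'   accuracy and corrected/naive SEM, and scheme metadata.
#' @export
loso_nested_cv <- function(d, grid = hyper_grid("pseudotrial"),
                           mode = c("pseudotrial", "single_trial"),
                           test_unit = c("pseudotrial", "single_trial"),
                           zscore_order = "average_then_zscore",
                           n_perm = 0, perm_seed = 1L) {
  mode <- match.arg(mode)
  test_unit <- match.arg(test_unit)
  subjects <- d$subject_ids
  if (length(subjects) < 3L) stop("nested LOSO needs at least 3 subjects")
  if (nrow(grid$combinations) == 0L) stop("empty hyperparameter grid")

  tr_units <- .prepare_units(d, mode, zscore_order)
  te_units <- if (test_unit == mode) tr_units else
    .prepare_units(d, test_unit, zscore_order)
  tr_rows <- split(seq_along(tr_units$groups), tr_units$groups)
  te_rows <- split(seq_along(te_units$groups), te_units$groups)

  D2_tr <- .sqdist(tr_units$x)
  D2_te <- if (test_unit == mode) D2_tr else
    .sqdist(te_units$x, tr_units$x)

  gammas <- sort(unique(grid$combinations$gamma))
  combos <- grid$combinations
  folds <- vector("list", length(subjects))

  for (k in seq_along(subjects)) {
    test_subj <- subjects[k]
    train_subj <- setdiff(subjects, test_subj)
    # inner LOSO validation accuracy per grid combination (trivially
    # skipped when there is nothing to select)
    val_acc <- matrix(0, nrow(combos), length(train_subj))
    for (j in if (nrow(combos) > 1L) seq_along(train_subj) else integer(0)) {
      val_subj <- train_subj[j]
      fit_subj <- setdiff(train_subj, val_subj)
      fit_idx <- unlist(tr_rows[fit_subj], use.names = FALSE)
      val_idx <- unlist(tr_rows[val_subj], use.names = FALSE)
      for (g in gammas) {
        Ktr <- exp(-g * D2_tr[fit_idx, fit_idx, drop = FALSE])
        Kva <- exp(-g * D2_tr[val_idx, fit_idx, drop = FALSE])
        rows <- which(combos$gamma == g)
        for (r in rows) {
          val_acc[r, j] <- .eval_fold(Ktr, tr_units$labels[fit_idx],
                                      Kva, tr_units$labels[val_idx],
                                      combos$c[r])$accuracy
        }
      }
    }
    best <- .select_combo(combos, rowMeans(val_acc))
    fit_idx <- unlist(tr_rows[train_subj], use.names = FALSE)
    te_idx <- unlist(te_rows[test_subj], use.names = FALSE)
    Ktr <- exp(-best$gamma * D2_tr[fit_idx, fit_idx, drop = FALSE])
    Kte <- exp(-best$gamma * D2_te[te_idx, fit_idx, drop = FALSE])
    res <- .eval_fold(Ktr, tr_units$labels[fit_idx],
                      Kte, te_units$labels[te_idx], best$c)
    p_perm <- NA_real_
    if (n_perm > 0) {
      p_perm <- permutation_test(te_units$labels[te_idx], res$pred,
                                 n_perm = n_perm,
                                 seed = perm_seed + k)
    }
    folds[[k]] <- data.frame(subject = test_subj,
                             accuracy = res$accuracy,
                             c = best$c, gamma = best$gamma,
                             n_test = length(te_idx),
                             p_perm = p_perm,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  .new_cv_result(folds, "nested_loso", mode, test_unit, grid,
                 n_train = mean(lengths(tr_rows)) * (length(subjects) - 1),
                 n_test = mean(folds$n_test))
}

#' Debiased double-holdout cross-validation
#'
#' In every iteration one subject is held out for validation and a
#' second for testing, so each classifier is trained on `n - 2`
#' subjects. Subjects are split into two halves; the per-iteration
#' optimal `(c, gamma)` found on validation subjects of one half are
#' averaged (arithmetic mean for `c`, geometric mean for `gamma`,
#' snapped to the nearest grid point) and the two resulting parameter
#' sets are transferred to score the test subjects of the opposite
#' half. Each subject serves as the test subject exactly once.
#'
#' With an odd number of subjects the first half holds `floor(n / 2)`
#' subjects; validation partners are assigned cyclically from the
#' opposite half.
#'
#' @inheritParams loso_nested_cv
#' @return A `cv_result`; `transferred_params` in the result records
#'   the two parameter sets and the half each was estimated from.
#' @export
loso_debiased_cv <- function(d, grid = hyper_grid("debiased"),
                             mode = c("single_trial", "pseudotrial"),
                             test_unit = c("single_trial", "pseudotrial"),
                             zscore_order = "average_then_zscore",
                             n_perm = 0, perm_seed = 1L) {
  mode <- match.arg(mode)
  test_unit <- match.arg(test_unit)
  subjects <- d$subject_ids
  n <- length(subjects)
  if (n < 4L) stop("debiased CV needs at least 4 subjects")

  tr_units <- .prepare_units(d, mode, zscore_order)
  te_units <- if (test_unit == mode) tr_units else
    .prepare_units(d, test_unit, zscore_order)
  tr_rows <- split(seq_along(tr_units$groups), tr_units$groups)
  te_rows <- split(seq_along(te_units$groups), te_units$groups)
  D2_tr <- .sqdist(tr_units$x)
  D2_te <- if (test_unit == mode) D2_tr else
    .sqdist(te_units$x, tr_units$x)

  half1 <- subjects[seq_len(n %/% 2)]
  half2 <- setdiff(subjects, half1)
  combos <- grid$combinations
  gammas <- sort(unique(combos$gamma))

  # pair each test subject with a cyclically chosen validation subject
  # from the opposite half
  pairs <- data.frame(test = subjects, val = NA_character_,
                      stringsAsFactors = FALSE)
  i1 <- which(pairs$test %in% half1)
  i2 <- which(pairs$test %in% half2)
  pairs$val[i1] <- half2[(seq_along(i1) - 1L) %% length(half2) + 1L]
  pairs$val[i2] <- half1[(seq_along(i2) - 1L) %% length(half1) + 1L]

  # per-iteration optimal parameters measured on the validation subject
  opt <- vector("list", n)
  for (k in seq_len(n)) {
    fit_subj <- setdiff(subjects, c(pairs$test[k], pairs$val[k]))
    fit_idx <- unlist(tr_rows[fit_subj], use.names = FALSE)
    val_idx <- unlist(tr_rows[pairs$val[k]], use.names = FALSE)
    acc <- numeric(nrow(combos))
    for (g in gammas) {
      Ktr <- exp(-g * D2_tr[fit_idx, fit_idx, drop = FALSE])
      Kva <- exp(-g * D2_tr[val_idx, fit_idx, drop = FALSE])
      rows <- which(combos$gamma == g)
      for (r in rows) {
        acc[r] <- .eval_fold(Ktr, tr_units$labels[fit_idx],
                             Kva, tr_units$labels[val_idx],
                             combos$c[r])$accuracy
      }
    }
    opt[[k]] <- cbind(.select_combo(combos, acc),
                      val = pairs$val[k], test = pairs$test[k])
  }
  opt <- do.call(rbind, opt)

  mean_params <- function(rows) {
    hyper_params(
      c = .snap_to_grid(mean(rows$c), grid$c_values),
      gamma = .snap_to_grid(exp(mean(log(rows$gamma))),
                            grid$gamma_values, log_scale = TRUE)
    )
  }
  # params estimated on half-1 validators score half-2 test subjects
  params_for_half2 <- mean_params(opt[opt$val %in% half1, ])
  params_for_half1 <- mean_params(opt[opt$val %in% half2, ])

  folds <- vector("list", n)
  for (k in seq_len(n)) {
    hp <- if (pairs$test[k] %in% half1) params_for_half1 else params_for_half2
    fit_subj <- setdiff(subjects, c(pairs$test[k], pairs$val[k]))
    fit_idx <- unlist(tr_rows[fit_subj], use.names = FALSE)
    te_idx <- unlist(te_rows[pairs$test[k]], use.names = FALSE)
    Ktr <- exp(-hp$gamma * D2_tr[fit_idx, fit_idx, drop = FALSE])
    Kte <- exp(-hp$gamma * D2_te[te_idx, fit_idx, drop = FALSE])
    res <- .eval_fold(Ktr, tr_units$labels[fit_idx],
                      Kte, te_units$labels[te_idx], hp$c)
    p_perm <- NA_real_
    if (n_perm > 0) {
      p_perm <- permutation_test(te_units$labels[te_idx], res$pred,
                                 n_perm = n_perm, seed = perm_seed + k)
    }
    folds[[k]] <- data.frame(subject = pairs$test[k],
                             validation_subject = pairs$val[k],
                             accuracy = res$accuracy,
                             c = hp$c, gamma = hp$gamma,
                             n_test = length(te_idx), p_perm = p_perm,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  .new_cv_result(
    folds, "debiased_loso", mode, test_unit, grid,
    n_train = mean(lengths(tr_rows)) * (n - 2),
    n_test = mean(folds$n_test),
    extra = list(
      transferred_params = list(for_half1_tests = params_for_half1,
                                for_half2_tests = params_for_half2),
      halves = list(half1 = half1, half2 = half2),
      per_validation_optima = opt
    )
  )
}

#' Oracle cross-validation (optimistic upper bound)
#'
#' Like [loso_nested_cv()] but the `(c, gamma)` pair for each held-out
#' subject is chosen to maximise that subject's own test accuracy, so
#' the resulting estimate is an optimistically biased upper level of
#' performance. The result is flagged `biased = TRUE`.
#'
#' @inheritParams loso_nested_cv
#' @return A `cv_result` with `biased = TRUE` in its metadata.
#' @export
oracle_cv <- function(d, grid = hyper_grid("pseudotrial"),
                      mode = c("pseudotrial", "single_trial"),
                      test_unit = c("pseudotrial", "single_trial"),
                      zscore_order = "average_then_zscore") {
  mode <- match.arg(mode)
  test_unit <- match.arg(test_unit)
  subjects <- d$subject_ids
  if (length(subjects) < 3L) stop("oracle CV needs at least 3 subjects")

  tr_units <- .prepare_units(d, mode, zscore_order)
  te_units <- if (test_unit == mode) tr_units else
    .prepare_units(d, test_unit, zscore_order)
  tr_rows <- split(seq_along(tr_units$groups), tr_units$groups)
  te_rows <- split(seq_along(te_units$groups), te_units$groups)
  D2_tr <- .sqdist(tr_units$x)
  D2_te <- if (test_unit == mode) D2_tr else
    .sqdist(te_units$x, tr_units$x)

  combos <- grid$combinations
  gammas <- sort(unique(combos$gamma))
  folds <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    train_subj <- setdiff(subjects, subjects[k])
    fit_idx <- unlist(tr_rows[train_subj], use.names = FALSE)
    te_idx <- unlist(te_rows[subjects[k]], use.names = FALSE)
    acc <- numeric(nrow(combos))
    for (g in gammas) {
      Ktr <- exp(-g * D2_tr[fit_idx, fit_idx, drop = FALSE])
      Kte <- exp(-g * D2_te[te_idx, fit_idx, drop = FALSE])
      rows <- which(combos$gamma == g)
      for (r in rows) {
        acc[r] <- .eval_fold(Ktr, tr_units$labels[fit_idx],
                             Kte, te_units$labels[te_idx],
                             combos$c[r])$accuracy
      }
    }
    best <- .select_combo(combos, acc)
    folds[[k]] <- data.frame(subject = subjects[k],
                             accuracy = max(acc),
                             c = best$c, gamma = best$gamma,
                             n_test = length(te_idx),
                             p_perm = NA_real_,
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  .new_cv_result(folds, "oracle", mode, test_unit, grid,
                 n_train = mean(lengths(tr_rows)) * (length(subjects) - 1),
                 n_test = mean(folds$n_test),
                 extra = list(biased = TRUE))
}
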