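#' Analytic gradient of the RBF decision function
#'
#' Derivative of `sum_n alpha_n k(x_n, x) + b` with respect to the
#' input `x`: per feature `j`,
#' `g_j = sum_n alpha_n * 2 * gamma * (x_{n,j} - x_j) * exp(-gamma * ||x_n - x||^2)`.
#' The bias contributes nothing.
#'
#' @param m A `kernel_model` from [svm_fit()].
#' @param x Feature vector at which to differentiate.
#' @return Numeric vector of the same length as `x`.
#' @export
kernel_gradient <- function(m, x) {
  if (length(x) != ncol(m$x))
    stop("feature length mismatch with training rows")
  k <- exp(-m$gamma * colSums((t(m$x) - x)^2))
  ak <- m$alphas * k
  2 * m$gamma * (as.vector(crossprod(m$x, ak)) - x * sum(ak))
}

#' Sensitivity map of a trained RBF-SVM
#'
#' Aggregates the analytic decision-function gradient over a set of
#' evaluation points into a channels x time importance map. The default
#' aggregation is the mean squared derivative (`mean_square`), giving a
#' nonnegative map in the probabilistic sensitivity-map convention; the
#' signed mean (`mean_signed`) is exposed for inspecting the direction
#' of each feature's influence. Evaluation points default to the
#' model's own training rows.
#'
#' @param m A `kernel_model`.
#' @param eval_points A `feature_matrix` (or matrix) of evaluation
#'   points; defaults to the training rows.
#' @param aggregation `"mean_square"` or `"mean_signed"`.
#' @return A [scalp_time_map()] of kind `"sensitivity"`.
#' @export
sensitivity_map <- function(m, eval_points = NULL,
                            aggregation = c("mean_square", "mean_signed")) {
  aggregation <- match.arg(aggregation)
  X_eval <- if (is.null(eval_points)) m$x
  else if (is.matrix(eval_points)) eval_points
  else eval_points$x
  if (nrow(X_eval) == 0L) stop("empty evaluation point set")
  if (ncol(X_eval) != ncol(m$x))
    stop("feature length mismatch with training rows")

  # all gradients at once: G[, j] is the gradient at eval point j
  K <- rbf_kernel_matrix(m$x, X_eval, m$gamma)   # n_train x n_eval
  A <- m$alphas * K
  colsum <- colSums(A)
  G <- 2 * m$gamma *
    (crossprod(m$x, A) - t(X_eval) * rep(colsum, each = ncol(m$x)))

  v <- if (aggregation == "mean_square") rowMeans(G^2) else rowMeans(G)
  n_ch <- length(m$channel_names)
  if (is.null(n_ch) || n_ch == 0L)
    stop("model carries no channel geometry; fit from a feature_matrix")
  scalp_time_map(matrix(v, nrow = n_ch), m$channel_names, m$times_ms,
                 kind = "sensitivity")
}
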