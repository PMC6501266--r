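#' Hyperparameter pair for the RBF SVM
#'
#' @param c Penalty (misclassification cost), positive.
#' @param gamma RBF kernel width parameter, positive.
#' @return A list of class `hyper_params`.
#' @export
hyper_params <- function(c, gamma) {
  if (c <= 0 || gamma <= 0) stop("c and gamma must be positive")
  structure(list(c = c, gamma = gamma), class = "hyper_params")
}

#' Hyperparameter search grids
#'
#' Builds the 10 x 10 logarithmically spaced search grid (endpoints
#' included) for a named preset, or from explicit value vectors:
#' \describe{
#'   \item{`single_trial`}{`c` in \[0.05, 10\], `gamma` in
#'     \[2.5e-7, 5e-3\].}
#'   \item{`debiased`, `pseudotrial`}{`c` in \[0.25, 15\], `gamma` in
#'     \[5e-7, 2.5e-2\].}
#' }
#'
#' @param preset Preset name, ignored when `c_values`/`gamma_values` are
#'   given.
#' @param c_values,gamma_values Optional explicit grids.
#' @return A list of class `hyper_grid` with `c_values`, `gamma_values`
#'   and the expanded `combinations` data frame (ordered by `c` then
#'   `gamma`, the tie-breaking order of grid search).
#' @export
hyper_grid <- function(preset = c("single_trial", "debiased", "pseudotrial"),
                       c_values = NULL, gamma_values = NULL) {
  if (is.null(c_values) || is.null(gamma_values)) {
    preset <- match.arg(preset)
    ranges <- switch(preset,
      single_trial = list(c = c(0.05, 10), gamma = c(2.5e-7, 5e-3)),
      debiased = ,
      pseudotrial = list(c = c(0.25, 15), gamma = c(5e-7, 2.5e-2))
    )
    logspace <- function(r, n = 10) exp(seq(log(r[1]), log(r[2]),
                                            length.out = n))
    if (is.null(c_values)) c_values <- logspace(ranges$c)
    if (is.null(gamma_values)) gamma_values <- logspace(ranges$gamma)
  } else {
    preset <- "custom"
  }
  if (any(c_values <= 0) || any(gamma_values <= 0))
    stop("grid values must be positive")
  combos <- expand.grid(gamma = gamma_values, c = c_values)[, c("c", "gamma")]
  combos <- combos[order(combos$c, combos$gamma), ]
  rownames(combos) <- NULL
  structure(list(preset = preset, c_values = c_values,
                 gamma_values = gamma_values, combinations = combos),
            class = "hyper_grid")
}

#' RBF kernel between two feature vectors
#'
#' `k(a, b) = exp(-gamma * ||a - b||^2)`, in (0, 1].
#'
#' @param a,b Numeric vectors of equal length.
#' @param gamma Positive kernel width parameter.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(a, b, gamma) {
  if (length(a) != length(b)) stop("length mismatch between a and b")
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((a - b)^2))
}

# Dense RBF kernel matrix K[i, j] = exp(-gamma * ||X[i,] - Y[j,]||^2),
# computed via the squared-norm expansion so BLAS does the heavy work.
rbf_kernel_matrix <- function(X, Y = NULL, gamma) {
  sqx <- rowSums(X^2)
  if (is.null(Y)) {
    K <- tcrossprod(X)
    K <- sqx - 2 * K
    K <- t(K) + sqx           # now ||xi||^2 + ||xj||^2 - 2 xi.xj
    K[K < 0] <- 0             # guard tiny negative rounding
    exp(-gamma * K)
  } else {
    sqy <- rowSums(Y^2)
    K <- tcrossprod(X, Y)
    K <- sqx - 2 * K
    K <- sweep(K, 2L, sqy, "+")
    K[K < 0] <- 0
    exp(-gamma * K)
  }
}

# Fit a C-SVC on a precomputed kernel matrix; returns the full-length
# signed dual vector (zeros retained) and bias, oriented so that
# sign(alpha_n) == y_n and positive decision values mean class +1.
fit_kernel_matrix <- function(K, y, c) {
  if (length(unique(y)) < 2L)
    stop("training data contains a single class")
  fac <- factor(y, levels = c(-1, 1))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), fac,
                     type = "C-svc", C = c, kernel = "matrix")
  co <- unlist(kernlab::coef(m))
  idx <- unlist(kernlab::alphaindex(m))
  s <- sign(co[1] * y[idx[1]])
  alphas <- numeric(length(y))
  alphas[idx] <- s * co
  list(alphas = alphas, b = -s * kernlab::b(m))
}

#' Fit an RBF-kernel SVM with exposed dual coefficients
#'
#' Trains a soft-margin C-SVC with the RBF kernel on a flattened
#' feature matrix and returns the dual-form model: the signed dual
#' coefficients `alpha` (one per training row, zeros retained for
#' non-support vectors, `sign(alpha_n) = y_n`, `|alpha_n| <= c`), the
#' bias `b`, and the stored training rows needed by the decision
#' function and sensitivity map. The quadratic program is solved by the
#' kernlab SMO implementation on a kernel matrix computed here.
#'
#' Rows are sorted canonically by (subject, trial) before fitting so
#' that the result is invariant to the input row order.
#'
#' @param train A `feature_matrix` from [flatten()], or a plain list
#'   with `x` (matrix), `labels` (-1/+1); `groups`/`trial` are used for
#'   the canonical sort when present.
#' @param hp A [hyper_params()] pair.
#' @return A list of class `kernel_model`: `alphas`, `b`, `gamma`, `c`,
#'   `x` (training rows), `y`, `n_support`, plus the feature geometry
#'   (`channel_names`, `times_ms`) when the input carries it.
#' @export
svm_fit <- function(train, hp) {
  stopifnot(is.matrix(train$x), length(train$labels) == nrow(train$x))
  ord <- seq_len(nrow(train$x))
  if (!is.null(train$groups)) {
    tr <- if (!is.null(train$trial)) train$trial else ord
    ord <- order(train$groups, tr)
  }
  X <- train$x[ord, , drop = FALSE]
  y <- train$labels[ord]
  K <- rbf_kernel_matrix(X, gamma = hp$gamma)
  fit <- fit_kernel_matrix(K, y, hp$c)
  structure(
    list(
      alphas = fit$alphas,
      b = fit$b,
      gamma = hp$gamma,
      c = hp$c,
      x = X,
      y = y,
      n_support = sum(fit$alphas != 0),
      groups = train$groups[ord],
      channel_names = train$channel_names,
      times_ms = train$times_ms
    ),
    class = "kernel_model"
  )
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf(
    "<kernel_model> %d training rows (%d support vectors), c = %g, gamma = %g\n",
    length(x$alphas), x$n_support, x$c, x$gamma))
  invisible(x)
}

#' Dual-form decision function
#'
#' Evaluates `f(x) = sum_n alpha_n k(x_n, x) + b` over all stored
#' training rows (zero coefficients contribute nothing). Positive
#' values vote for the animate class (+1).
#'
#' @param m A `kernel_model`.
#' @param x A feature vector, or a matrix with one row per evaluation
#'   point.
#' @return Numeric vector of decision values.
#' @export
decision_function <- function(m, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(m$x))
    stop("feature length mismatch with training rows")
  K <- rbf_kernel_matrix(x, m$x, m$gamma)
  as.vector(K %*% m$alphas) + m$b
}

#' Predict animacy labels
#'
#' Sign of the decision function; an exact zero is assigned to the
#' inanimate majority class (-1).
#'
#' @param object A `kernel_model`.
#' @param x Feature vector or matrix of rows.
#' @param ... Unused.
#' @return Vector of -1/+1 labels.
#' @export
predict.kernel_model <- function(object, x, ...) {
  dv <- decision_function(object, x)
  ifelse(dv > 0, 1, -1)
}
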