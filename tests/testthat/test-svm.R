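test_that("rbf_kernel matches hand-evaluated values and limits", {
  a <- c(0, 0); b <- c(2, 0)   # squared distance 4
  expect_equal(rbf_kernel(a, b, 0.25), exp(-1), tolerance = 1e-12)
  expect_equal(rbf_kernel(a, a, 3.7), 1)
  expect_equal(rbf_kernel(a, b, 1e-12), 1, tolerance = 1e-9)
  expect_error(rbf_kernel(a, c(1, 2, 3), 1), "length mismatch")
  # matrix form agrees with the scalar definition
  X <- matrix(rnorm(12), 4, 3)
  K <- eegdecode:::rbf_kernel_matrix(X, gamma = 0.3)
  for (i in 1:4) for (j in 1:4)
    expect_equal(K[i, j], rbf_kernel(X[i, ], X[j, ], 0.3),
                 tolerance = 1e-12)
})

test_that("hyperparameter grids hold 100 log-spaced combinations", {
  for (preset in c("single_trial", "debiased", "pseudotrial")) {
    g <- hyper_grid(preset)
    expect_equal(nrow(g$combinations), 100L)
    expect_length(g$c_values, 10L)
    # log-spacing: constant ratio between neighbours
    r <- diff(log(g$gamma_values))
    expect_equal(max(r) - min(r), 0, tolerance = 1e-12)
  }
  g <- hyper_grid("single_trial")
  expect_equal(range(g$c_values), c(0.05, 10))
  expect_equal(range(g$gamma_values), c(2.5e-7, 5e-3))
  g2 <- hyper_grid("pseudotrial")
  expect_equal(range(g2$c_values), c(0.25, 15))
  expect_equal(range(g2$gamma_values), c(5e-7, 2.5e-2))
})

test_that("fitted dual coefficients satisfy the box and sign constraints", {
  d <- tiny_dataset()
  fm <- flatten(zscore_trials(d))
  hp <- hyper_params(c = 0.8, gamma = 1e-4)
  m <- svm_fit(fm, hp)
  expect_length(m$alphas, nrow(fm$x))
  expect_lte(max(abs(m$alphas)), hp$c + 1e-8)
  expect_equal(m$n_support, sum(m$alphas != 0))
  nz <- m$alphas != 0
  expect_true(all(sign(m$alphas[nz]) == m$y[nz]))
  # KKT balance: the alphas of the two classes sum to zero
  expect_lt(abs(sum(m$alphas)), 1e-6)
})

test_that("decision function equals the brute-force dual sum", {
  d <- tiny_dataset(n_subjects = 3, trials_per_category = 2)
  fm <- flatten(zscore_trials(d))
  m <- svm_fit(fm, hyper_params(1, 2e-4))
  x0 <- fm$x[7, ]
  brute <- sum(vapply(seq_len(nrow(m$x)), function(n) {
    m$alphas[n] * rbf_kernel(m$x[n, ], x0, m$gamma)
  }, numeric(1))) + m$b
  expect_equal(decision_function(m, x0), brute, tolerance = 1e-10)
  # margin consistency on confidently classified training points
  dv <- decision_function(m, m$x)
  conf <- abs(dv) > 1
  expect_true(all(predict(m, m$x)[conf] == sign(dv)[conf]))
})

test_that("hand-built models behave analytically", {
  # single support vector at the origin with alpha = 1, b = 0
  m <- toy_model(x = matrix(0, 1, 2), alphas = 1, b = 0, gamma = 0.7)
  expect_equal(decision_function(m, c(0, 0)), 1)
  # shifting b shifts the decision value exactly
  m_shift <- m; m_shift$b <- 0.25
  expect_equal(decision_function(m_shift, c(1, 1)),
               decision_function(m, c(1, 1)) + 0.25)
  # exact zero decision value goes to the inanimate class
  m0 <- toy_model(x = matrix(0, 1, 2), alphas = 1, b = -1, gamma = 0.7)
  expect_equal(decision_function(m0, c(0, 0)), 0)
  expect_equal(predict(m0, c(0, 0)), -1)
})

test_that("a separable two-point problem is classified perfectly", {
  train <- list(x = rbind(c(0, 0), c(10, 10)), labels = c(-1, 1))
  m <- svm_fit(train, hyper_params(10, 0.05))
  expect_equal(predict(m, train$x), c(-1, 1))
})

test_that("fitting is invariant to training-row order", {
  d <- tiny_dataset(n_subjects = 3)
  fm <- flatten(zscore_trials(d))
  perm <- sample(nrow(fm$x))
  fm_perm <- fm
  fm_perm$x <- fm$x[perm, ]
  fm_perm$labels <- fm$labels[perm]
  fm_perm$groups <- fm$groups[perm]
  fm_perm$trial <- fm$trial[perm]
  hp <- hyper_params(1, 2e-4)
  m1 <- svm_fit(fm, hp)
  m2 <- svm_fit(fm_perm, hp)
  expect_identical(m1$alphas, m2$alphas)
  expect_identical(m1$b, m2$b)
})

test_that("the fitted model agrees with an independent libsvm solve", {
  # same QP solved by a different implementation: decision values and
  # predictions must coincide on a non-degenerate problem
  d <- tiny_dataset(n_subjects = 3, effect_amplitude = 2)
  fm <- flatten(zscore_trials(d))
  hp <- hyper_params(c = 2, gamma = 3e-4)
  m <- svm_fit(fm, hp)
  ref <- e1071::svm(fm$x, factor(fm$labels, levels = c(-1, 1)),
                    kernel = "radial", gamma = hp$gamma, cost = hp$c,
                    scale = FALSE)
  dv_ref <- attr(predict(ref, fm$x, decision.values = TRUE),
                 "decision.values")
  # libsvm orients its decision by the first label in the data; align
  s <- sign(cor(as.vector(dv_ref), fm$labels))
  dv <- decision_function(m, fm$x)
  expect_equal(dv, s * as.vector(dv_ref), tolerance = 1e-3)
  pred_ref <- as.numeric(as.character(predict(ref, fm$x)))
  expect_equal(predict(m, fm$x), pred_ref)
})

test_that("single-class training data is rejected", {
  train <- list(x = matrix(rnorm(20), 10, 2), labels = rep(1, 10))
  expect_error(svm_fit(train, hyper_params(1, 0.1)), "single class")
})
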