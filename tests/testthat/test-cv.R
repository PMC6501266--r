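# Small grids keep the CV schemes fast; the full 10 x 10 presets are
# exercised through their structure in test-svm.R.
cv_grid <- function() hyper_grid(c_values = c(0.25, 15),
                                 gamma_values = c(1e-4, 1e-3))

test_that("nested LOSO holds out each subject exactly once", {
  d <- tiny_dataset(n_subjects = 5)
  cv <- loso_nested_cv(d, cv_grid(), mode = "pseudotrial",
                       test_unit = "pseudotrial")
  expect_identical(sort(cv$folds$subject), sort(d$subject_ids))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  expect_equal(cv$folds$n_test, rep(5L, 5))  # 5 categories as pseudotrials
  expect_error(loso_nested_cv(subset_subjects(d, c("S01", "S02")),
                              cv_grid()), "3 subjects")
})

test_that("a strongly planted effect is decoded almost perfectly", {
  d <- tiny_dataset(n_subjects = 5, trials_per_category = 8,
                    effect_amplitude = 4, noise_sd = 0.5)
  cv <- loso_nested_cv(d, cv_grid(), mode = "pseudotrial",
                       test_unit = "pseudotrial")
  expect_gt(cv$summary$mean_accuracy, 0.9)
})

test_that("single-trial test units are scored per trial", {
  d <- tiny_dataset(n_subjects = 4)
  cv <- loso_nested_cv(d, cv_grid(), mode = "pseudotrial",
                       test_unit = "single_trial")
  expect_equal(cv$folds$n_test, rep(20L, 4))  # 5 categories x 4 trials
  expect_identical(cv$test_unit, "single_trial")
})

test_that("debiased CV transfers exactly two parameter sets across halves", {
  d <- tiny_dataset(n_subjects = 6, trials_per_category = 6,
                    effect_amplitude = 2)
  cv <- loso_debiased_cv(d, cv_grid(), mode = "pseudotrial",
                         test_unit = "pseudotrial")
  expect_equal(nrow(cv$folds), 6L)
  expect_identical(sort(cv$folds$subject), sort(d$subject_ids))
  # validation partner always comes from the opposite half
  h1 <- cv$halves$half1
  expect_true(all((cv$folds$subject %in% h1) !=
                    (cv$folds$validation_subject %in% h1)))
  tp <- cv$transferred_params
  expect_s3_class(tp$for_half1_tests, "hyper_params")
  expect_s3_class(tp$for_half2_tests, "hyper_params")
  # transferred values are snapped onto the grid
  g <- cv_grid()
  expect_true(tp$for_half1_tests$c %in% g$c_values)
  expect_true(tp$for_half2_tests$gamma %in% g$gamma_values)
  expect_error(loso_debiased_cv(subset_subjects(d, c("S01", "S02", "S03")),
                                cv_grid()), "4 subjects")
})

test_that("a single-combination grid reduces debiased CV to fixed-parameter LOSO", {
  d <- tiny_dataset(n_subjects = 5)
  g1 <- hyper_grid(c_values = 2, gamma_values = 3e-4)
  cv <- loso_debiased_cv(d, g1, mode = "pseudotrial",
                         test_unit = "pseudotrial")
  expect_true(all(cv$folds$c == 2))
  expect_true(all(cv$folds$gamma == 3e-4))
})

test_that("oracle CV upper-bounds nested CV on the same grid", {
  d <- tiny_dataset(n_subjects = 5, trials_per_category = 6,
                    effect_amplitude = 1)
  g <- cv_grid()
  nested <- loso_nested_cv(d, g, mode = "pseudotrial",
                           test_unit = "pseudotrial")
  oracle <- oracle_cv(d, g, mode = "pseudotrial",
                      test_unit = "pseudotrial")
  expect_true(isTRUE(oracle$biased))
  expect_true(all(oracle$folds$accuracy >= nested$folds$accuracy))
  # a single-combination grid makes the two schemes identical
  g1 <- hyper_grid(c_values = 2, gamma_values = 3e-4)
  n1 <- loso_nested_cv(d, g1, mode = "pseudotrial",
                       test_unit = "pseudotrial")
  o1 <- oracle_cv(d, g1, mode = "pseudotrial", test_unit = "pseudotrial")
  expect_equal(o1$folds$accuracy, n1$folds$accuracy)
})

test_that("oracle selection exceeds the majority baseline on null data", {
  d <- tiny_dataset(n_subjects = 5, trials_per_category = 6,
                    effect_amplitude = 0, rng_seed = 9)
  baseline <- 3 / 5  # inanimate majority share of categories
  o <- oracle_cv(d, cv_grid(), mode = "pseudotrial",
                 test_unit = "pseudotrial")
  expect_gte(o$summary$mean_accuracy, baseline)
})

test_that("grid-search ties break towards the smallest c then gamma", {
  combos <- hyper_grid(c_values = c(1, 0.1), gamma_values = c(2, 0.2))
  expect_equal(combos$combinations$c, c(0.1, 0.1, 1, 1))
  expect_equal(combos$combinations$gamma, c(0.2, 2, 0.2, 2))
  best <- eegdecode:::.select_combo(combos$combinations, c(0.5, 0.5, 0.5, 0.5))
  expect_equal(best$c, 0.1)
  expect_equal(best$gamma, 0.2)
})
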