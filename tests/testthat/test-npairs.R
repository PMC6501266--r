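test_that("splits are disjoint, sized, and reproducible", {
  ids <- sprintf("S%02d", 1:15)
  cfg <- npairs_config(n_splits = 20, partition_size = 7, rng_seed = 3)
  splits <- make_splits(ids, cfg)
  expect_length(splits, 20L)
  for (sp in splits) {
    expect_length(sp$partition1, 7L)
    expect_length(sp$partition2, 7L)
    expect_length(intersect(sp$partition1, sp$partition2), 0L)
    expect_length(sp$left_out, 1L)   # 15 subjects, 7 + 7 used
  }
  expect_identical(splits, make_splits(ids, cfg))
  # constraint arithmetic
  expect_length(make_splits(letters[1:4],
                            npairs_config(3, 2, 1)), 3L)
  expect_error(make_splits(letters[1:4], npairs_config(3, 3, 1)),
               "partition constraint")
})

test_that("the split-half sigma and effect size match the hand example", {
  # S = 2 splits of 1x1 maps: (M1, M2) = (1, 0) then (0, 2); full map 1
  d <- manual_dataset(array(rnorm(2 * 2 * 3), c(2, 2, 3)),
                      array(rnorm(2 * 2 * 3), c(2, 2, 3)))
  vals <- list(1, 0, 0, 2)
  call_no <- 0
  map_fn <- function(data, subjects) {
    if (length(subjects) == length(d$subject_ids)) {
      v <- 1  # full-data map
    } else {
      call_no <<- call_no + 1
      v <- vals[[call_no]]
    }
    scalp_time_map(matrix(v), "O1", 0, kind = "erp_difference")
  }
  res <- npairs_effect_size(d, map_fn,
                            npairs_config(n_splits = 2,
                                          partition_size = 1, rng_seed = 1))
  expect_equal(res$sigma, sqrt(2.5), tolerance = 1e-6)   # 1.58114
  expect_equal(res$effect_map$values[1, 1], 1 / sqrt(2.5),
               tolerance = 1e-6)                          # 0.63246
})

test_that("identical partition maps are flagged as degenerate", {
  d <- manual_dataset(array(rnorm(12), c(2, 2, 3)),
                      array(rnorm(12), c(2, 2, 3)))
  const_fn <- function(data, subjects)
    scalp_time_map(matrix(7), "O1", 0, kind = "erp_difference")
  expect_error(
    npairs_effect_size(d, const_fn, npairs_config(2, 1, 1)),
    "degenerate resampling")
})

test_that("effect maps of a linear map_fn are invariant to data rescaling", {
  d <- tiny_dataset(n_subjects = 6, trials_per_category = 3)
  cfg <- npairs_config(n_splits = 8, partition_size = 3, rng_seed = 2)
  res1 <- npairs_effect_size(d, erp_difference_mapper(), cfg)
  d_scaled <- d
  d_scaled$data <- 3.5 * d$data
  res2 <- npairs_effect_size(d_scaled, erp_difference_mapper(), cfg)
  expect_equal(res2$sigma, 3.5 * res1$sigma, tolerance = 1e-10)
  expect_equal(res2$full_map$values, 3.5 * res1$full_map$values,
               tolerance = 1e-10)
  expect_equal(res2$effect_map$values, res1$effect_map$values,
               tolerance = 1e-10)
})

test_that("sigma is stable across resampling seeds", {
  d <- tiny_dataset(n_subjects = 8, trials_per_category = 4)
  s1 <- npairs_effect_size(d, erp_difference_mapper(),
                           npairs_config(100, 4, 11))$sigma
  s2 <- npairs_effect_size(d, erp_difference_mapper(),
                           npairs_config(100, 4, 99))$sigma
  expect_lt(abs(s1 - s2) / s1, 0.15)
})

test_that("the SVM sensitivity mapper plugs into the resampling scheme", {
  d <- tiny_dataset(n_subjects = 6, trials_per_category = 4,
                    effect_amplitude = 2)
  res <- npairs_effect_size(
    d, sensitivity_mapper(hyper_params(7.2, 3.7e-4), mode = "pseudotrial"),
    npairs_config(n_splits = 3, partition_size = 3, rng_seed = 5))
  expect_s3_class(res$effect_map, "scalp_time_map")
  expect_identical(res$effect_map$kind, "effect_size")
  expect_gt(res$sigma, 0)
  expect_equal(res$effect_map$values,
               res$full_map$values / res$sigma, tolerance = 1e-12)
})

test_that("single- and pseudotrial sensitivity maps agree over the effect window", {
  # the effect-size scaling divides by a positive scalar, so spatial
  # correlation of the scaled maps equals that of the raw maps
  d <- generate_dataset(simulation_config(
    n_subjects = 8, trials_per_category = 8, rng_seed = 6))
  cfg <- simulation_config()
  m_single <- svm_fit(eegdecode:::.prepare_units(d, "single_trial"),
                      hyper_params(1.5, 5e-5))
  m_pseudo <- svm_fit(eegdecode:::.prepare_units(d, "pseudotrial"),
                      hyper_params(7.2, 3.7e-4))
  s1 <- sensitivity_map(m_single)
  s2 <- sensitivity_map(m_pseudo)
  win <- d$times_ms >= cfg$effect_window_ms[1] &
    d$times_ms <= cfg$effect_window_ms[2]
  expect_gt(cor(as.vector(s1$values[, win]), as.vector(s2$values[, win])),
            0.5)
})
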