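# Shared fixtures: all test data is generated in code.

# Small paradigm for fast unit tests: 4 subjects, 5 categories (2
# animate) x 4 trials, full 32-channel montage, 60-sample epochs.
tiny_cfg <- function(...) {
  args <- list(n_subjects = 4, n_categories = 5,
               n_animate_categories = 2, trials_per_category = 4,
               noise_sd = 1, rng_seed = 42)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

tiny_dataset <- function(...) generate_dataset(tiny_cfg(...))

# Hand-built kernel model for analytic checks.
toy_model <- function(x, alphas, b, gamma,
                      channel_names = NULL, times_ms = NULL) {
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(x)))
  if (is.null(times_ms)) times_ms <- 0
  structure(list(alphas = alphas, b = b, gamma = gamma, x = x,
                 y = ifelse(alphas >= 0, 1, -1),
                 c = max(abs(alphas), 1), n_support = sum(alphas != 0),
                 channel_names = channel_names, times_ms = times_ms),
            class = "kernel_model")
}

# Minimal two-category dataset with fully prescribed trial values:
# `animate_vals` and `inanimate_vals` are (subject x channel x time)
# arrays (or a function of subject index) assigned to single trials.
manual_dataset <- function(animate_vals, inanimate_vals,
                           channel_names = c("O1", "Cz"),
                           times_ms = c(0, 10, 20)) {
  n_s <- dim(animate_vals)[1]
  n_ch <- length(channel_names); n_t <- length(times_ms)
  data <- array(0, dim = c(n_s, 2, n_ch, n_t))
  data[, 1, , ] <- animate_vals
  data[, 2, , ] <- inanimate_vals
  epoched_eeg(
    data,
    subject_ids = sprintf("S%02d", seq_len(n_s)),
    category_labels = matrix(rep(c(1L, 2L), each = n_s), n_s, 2),
    animacy_labels = matrix(rep(c(1, -1), each = n_s), n_s, 2),
    channel_names = channel_names, times_ms = times_ms,
    sampling_rate_hz = 100
  )
}

# All permutations of seq_len(n) (for exhaustive permutation-test
# enumeration at tiny n).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
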