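# Small study fixtures shared across test files. Sessions are generated at
# reduced size/rate so each file stays fast; full-scale runs live in
# test-acceptance.R.

small_spec <- function(...) {
  args <- list(fs = 200, n_trials_per_condition = 6, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# epochs of two-class AR(2) trials with per-channel independent dynamics;
# used to exercise feature extraction and decoding without the full pipeline
ar_epochs <- function(n_per = 20, f0 = c(0.8, 3.4), bw = 0.3, C = 4,
                      T_len = 100, fs = 100, seed = 1,
                      opposite = rep("F", 2 * n_per)) {
  withr::with_seed(seed, {
    n <- 2 * n_per
    lab <- rep(c("L", "R"), each = n_per)
    arr <- array(0, c(n, C, T_len))
    for (tr in seq_len(n)) {
      cf <- esndecode:::ar2_coef(if (lab[tr] == "L") f0[1] else f0[2],
                                 fs, bw)
      for (ch in seq_len(C)) {
        x <- as.numeric(stats::filter(stats::rnorm(3 * T_len), cf,
                                      method = "recursive"))
        x <- x[(2 * T_len + 1):(3 * T_len)]
        arr[tr, ch, ] <- (x - mean(x)) / stats::sd(x)
      }
    }
    new_epochs(arr, fs, default_montage()[seq_len(C)],
               (seq_len(T_len) - 1) / fs,
               data.frame(primary = lab, opposite = opposite,
                          stringsAsFactors = FALSE))
  })
}

# plain Gaussian-noise epochs (no class information)
noise_epochs <- function(n = 40, C = 3, T_len = 60, fs = 100, seed = 5) {
  withr::with_seed(seed, {
    arr <- array(stats::rnorm(n * C * T_len), c(n, C, T_len))
    new_epochs(arr, fs, default_montage()[seq_len(C)],
               (seq_len(T_len) - 1) / fs,
               data.frame(primary = rep(c("L", "R"), length.out = n),
                          opposite = rep(rep(c("F", "B"), each = 2),
                                         length.out = n),
                          stringsAsFactors = FALSE))
  })
}
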