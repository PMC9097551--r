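make_rec <- function(data, fs = 100, ch_types = NULL,
                     go = ncol(data) %/% 2) {
  if (is.null(ch_types)) ch_types <- rep("eeg", nrow(data))
  new_recording(data, fs, ch_types,
                data.frame(trial = 1, cue_sample = 1, go_sample = go,
                           onset_sample = go, primary = "L",
                           opposite = "F"))
}

test_that("down-sampling preserves duration, DC level and slow content", {
  spec <- small_spec(fs = 1000, n_trials_per_condition = 1)
  rec <- generate_session(spec)
  out <- resample_recording(rec, 100)
  expect_equal(ncol(out$data), ncol(rec$data) / 10)   # 11 s -> 1100 samples
  expect_equal(out$fs, 100)
  expect_equal(out$events$go_sample,
               as.integer(round((rec$events$go_sample - 1) / 10) + 1))

  const <- make_rec(matrix(5, 2, 11000, dimnames = list(c("a", "b"), NULL)),
                    fs = 1000)
  cdown <- resample_recording(const, 100)
  expect_lt(max(abs(cdown$data - 5)), 1e-6)

  t <- (0:10999) / 1000
  sine <- make_rec(matrix(sin(2 * pi * 2 * t), 1, 11000,
                          dimnames = list("s", NULL)), fs = 1000)
  sdown <- resample_recording(sine, 100)
  ideal <- sin(2 * pi * 2 * (0:1099) / 100)
  expect_gt(stats::cor(sdown$data[1, ], ideal), 0.999)

  expect_error(resample_recording(const, 2000), "upsampling")
})

test_that("re-referencing subtracts the mean of the reference channels", {
  d <- matrix(rnorm(4 * 50), 4, 50,
              dimnames = list(c("Cz", "C1", "M1", "M2"), NULL))
  rec <- make_rec(d, ch_types = c("eeg", "eeg", "ref", "ref"))

  zero_ref <- rec
  zero_ref$data[3:4, ] <- 0
  expect_equal(rereference(zero_ref, c("M1", "M2"))$data, zero_ref$data)

  const_ref <- rec
  const_ref$data[3, ] <- 2
  const_ref$data[4, ] <- 4
  shifted <- rereference(const_ref, c("M1", "M2"))
  expect_equal(shifted$data[1:2, ], const_ref$data[1:2, ] - 3)

  out <- rereference(rec, c("M1", "M2"))
  expect_equal(colMeans(out$data[3:4, ]), rep(0, 50))
  expect_error(rereference(rec, c("A1", "A2")), "not present")
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  ep <- noise_epochs(n = 8, C = 3, T_len = 200)
  ep$times <- ep$times - 1                       # cover [-1, 1)
  out <- baseline_correct(ep, c(-1, 0))
  sel <- out$times >= -1 & out$times < 0
  expect_lt(max(abs(apply(out$data[, , sel], c(1, 2), mean))), 1e-9)
  twice <- baseline_correct(out, c(-1, 0))
  expect_equal(twice$data, out$data, tolerance = 1e-9)
  expect_error(baseline_correct(ep, c(5, 6)), "baseline")
})

test_that("common average reference zeroes the cross-channel mean", {
  ep <- noise_epochs(n = 6, C = 4, T_len = 50)
  out <- common_average_reference(ep)
  expect_lt(max(abs(apply(out$data, c(1, 3), mean))), 1e-9)
  # identical channels are cancelled entirely
  same <- ep
  for (ch in 2:4) same$data[, ch, ] <- same$data[, 1, ]
  expect_lt(max(abs(common_average_reference(same)$data)), 1e-9)
  # two channels -> (a-b)/2, (b-a)/2
  two <- noise_epochs(n = 3, C = 2, T_len = 30)
  o2 <- common_average_reference(two)
  expect_equal(o2$data[, 1, ], (two$data[, 1, ] - two$data[, 2, ]) / 2)
  expect_equal(o2$data[, 2, ], -o2$data[, 1, ])
  # idempotent
  expect_equal(common_average_reference(out)$data, out$data,
               tolerance = 1e-9)
})

test_that("band-pass dialects behave as specified and the FFT mask is linear", {
  fs <- 100
  t <- (0:999) / fs
  s10 <- sin(2 * pi * 10 * t)
  s2 <- sin(2 * pi * 2 * t)
  rms <- function(x) sqrt(mean(x^2))
  out10 <- bandpass(s10, c(0.01, 4), fs, "fft")
  expect_lt(rms(out10), 0.01 * rms(s10))
  out2 <- bandpass(s2, c(0.01, 4), fs, "fft")
  expect_equal(rms(out2), rms(s2), tolerance = 0.01)

  mix <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 3 * t + 1)
  fftv <- bandpass(mix, c(0.01, 4), fs, "fft")
  bwv <- bandpass(mix, c(0.01, 4), fs, "butterworth")
  expect_gt(stats::cor(fftv, bwv), 0.95)

  a <- rnorm(500)
  b <- rnorm(500)
  lin <- bandpass(2 * a + 3 * b, c(1, 10), fs, "fft")
  sep <- 2 * bandpass(a, c(1, 10), fs, "fft") +
    3 * bandpass(b, c(1, 10), fs, "fft")
  expect_equal(lin, sep, tolerance = 1e-9)

  expect_error(bandpass(s2, c(1, 60), fs), "Nyquist")
})

test_that("weighted average filter subtracts the weighted background", {
  ep <- noise_epochs(n = 4, C = 4, T_len = 80)
  # identical channels -> Cz becomes 0 under any valid weights
  same <- ep
  for (ch in 2:4) same$data[, ch, ] <- same$data[, 1, ]
  w <- c(C1 = 0.5, C2 = 0.25, C3 = 0.25)
  out <- weighted_average_filter_cz(same, w)
  ci <- match("Cz", out$ch_names)
  expect_lt(max(abs(out$data[, ci, ])), 1e-9)
  # one-hot weights -> Cz - C1
  onehot <- weighted_average_filter_cz(ep, c(C1 = 1, C2 = 0, C3 = 0))
  expect_equal(onehot$data[, ci, ],
               ep$data[, ci, ] - ep$data[, match("C1", ep$ch_names), ])
  expect_error(weighted_average_filter_cz(ep, c(C1 = 0.5, C2 = 0.1,
                                                C3 = 0.1)), "sum to 1")
})

test_that("default background weights do not inflate Cz variance", {
  spec <- synthetic_spec(fs = 200, n_trials_per_condition = 15, seed = 4)
  rec <- generate_session(spec)
  ep <- extract_epochs(rec, c(-2, 1.5))
  out <- weighted_average_filter_cz(ep)
  ci <- match("Cz", ep$ch_names)
  v_in <- stats::var(as.vector(ep$data[, ci, ]))
  v_out <- stats::var(as.vector(out$data[, ci, ]))
  expect_lt(v_out, 1.05 * v_in)
})

test_that("z-scoring normalizes per trial/channel and is affine-invariant", {
  ep <- noise_epochs(n = 5, C = 3, T_len = 40)
  out <- zscore_epochs(ep)
  mu <- apply(out$data, c(1, 2), mean)
  sdev <- apply(out$data, c(1, 2), function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(sdev - 1)), 1e-9)

  aff <- ep
  aff$data <- 3.2 * aff$data + 40
  expect_equal(zscore_epochs(aff)$data, out$data, tolerance = 1e-9)

  flat <- ep
  flat$data[2, 1, ] <- 7
  expect_error(zscore_epochs(flat), "trial 2, channel Cz")
})

test_that("epoching follows the half-open window convention", {
  spec <- small_spec(n_trials_per_condition = 2)
  rec <- generate_session(spec)
  ep1 <- extract_epochs(rec, c(0, 1))
  expect_equal(dim(ep1$data)[3], spec$fs)
  ep2 <- extract_epochs(rec, c(-1.5, 1.5))
  expect_equal(dim(ep2$data)[3], 3 * spec$fs)
  # first sample of a [0, x) window is the Go-Cue sample
  go <- rec$events$go_sample[1]
  expect_equal(ep1$data[1, 1, 1], rec$data[1, go])
  expect_equal(ep1$labels$primary, rec$events$primary)
  expect_error(extract_epochs(rec, c(-10, 1)), "trial")
})

test_that("ICA removes known blink contamination and spares clean data", {
  spec <- synthetic_spec(fs = 200, n_trials_per_condition = 4,
                         eog_rate = 0.3, seed = 13)
  rec <- generate_session(spec)
  fz <- match("Fz", rec$ch_names)
  eogi <- match("EOG1", rec$ch_names)
  pre_cor <- abs(stats::cor(rec$data[fz, ], rec$data[eogi, ]))
  res <- suppressWarnings(ica_eog_reject(rec, threshold = 0.4))
  expect_gt(length(res$rejected), 0)
  post_cor <- abs(stats::cor(res$recording$data[fz, ],
                             res$recording$data[eogi, ]))
  expect_lt(post_cor, pre_cor)
  # EOG channels are untouched
  expect_identical(res$recording$data[eogi, ], rec$data[eogi, ])

  # threshold 1: nothing can exceed it; reconstruction is lossless
  res1 <- suppressWarnings(ica_eog_reject(rec, threshold = 1))
  expect_length(res1$rejected, 0)
  rel_err <- max(abs(res1$recording$data[1:24, ] - rec$data[1:24, ])) /
    max(abs(rec$data[1:24, ]))
  expect_lt(rel_err, 1e-6)
})

test_that("blink-free sessions yield essentially no rejections", {
  rejections <- vapply(1:5, function(s) {
    spec <- synthetic_spec(fs = 200, n_trials_per_condition = 3,
                           eog_rate = 0, seed = 100 + s)
    length(suppressWarnings(
      ica_eog_reject(generate_session(spec), 0.4))$rejected)
  }, numeric(1))
  expect_lte(sum(rejections), 1)
})

test_that("the preprocessing chain records its provenance in order", {
  spec <- small_spec(n_trials_per_condition = 2)
  ep <- suppressWarnings(
    preprocess_recording(generate_session(spec), preprocess_config()))
  steps <- vapply(ep$provenance, `[[`, "", "step")
  expect_equal(steps, c("resample", "rereference", "baseline_correct",
                        "common_average_reference", "ica_eog_reject",
                        "bandpass", "extract_epochs", "zscore"))
})
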