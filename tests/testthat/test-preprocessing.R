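make_rec <- function(signals, fs = 2000, hs = c(0, 1)) {
  emg_recording(signals, fs, hs)
}

test_that("the envelope chain maps zero to zero and is positively homogeneous", {
  x <- matrix(0, 2, 4000)
  env0 <- emg_envelope(make_rec(x))
  expect_equal(max(abs(env0$signals)), 0)
  set.seed(42)
  y <- matrix(rnorm(2 * 4000), 2)
  e1 <- emg_envelope(make_rec(y))$signals
  e3 <- emg_envelope(make_rec(3 * y))$signals
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
})

test_that("the chain recovers a slow amplitude modulator from a fast carrier", {
  fs <- 2000
  t <- (0:(6 * fs - 1)) / fs
  modulator <- 0.6 + 0.4 * sin(2 * pi * 1 * t)
  sig <- rbind(sin(2 * pi * 100 * t) * modulator)
  env <- emg_envelope(make_rec(sig, fs, c(0, 6)))
  mid <- (fs):(5 * fs)  # drop one second of transient at each end
  expect_gt(cor(env$signals[1, mid], modulator[mid]), 0.95)
})

test_that("rectifying before low-pass is not interchangeable with the reverse", {
  fs <- 2000
  t <- (0:(4 * fs - 1)) / fs
  sig <- sin(2 * pi * 100 * t) * (0.6 + 0.4 * sin(2 * pi * 1 * t))
  chain <- emg_envelope(make_rec(rbind(sig), fs))$signals[1, ]
  lp <- signal::butter(6, 6 / (fs / 2), type = "low")
  swapped <- abs(signal::filtfilt(lp, sig - mean(sig)))
  mid <- (fs):(3 * fs)
  expect_gt(mean(abs(chain[mid] - swapped[mid])), 0.1)
})

test_that("cycles are resampled to the requested grid", {
  fs <- 2000
  const <- matrix(2.5, 3, 3 * fs)
  cycles <- segment_cycles(make_rec(const, fs, c(0, 0.9, 2.1)), n_samples = 101)
  expect_length(cycles, 2L)
  for (cyc in cycles) {
    expect_identical(dim(cyc), c(3L, 101L))
    expect_equal(max(abs(cyc - 2.5)), 0)
  }
  one <- segment_cycles(make_rec(const[, 1:1500, drop = FALSE], fs, c(0, 0.5)),
                        n_samples = 101)
  expect_identical(ncol(one[[1]]), 101L)
})

test_that("identical cycles of different durations normalise identically", {
  fs <- 8000
  d1 <- 1.0; d2 <- 1.3
  t <- (0:((d1 + d2) * fs)) / fs
  phase <- ifelse(t < d1, t / d1, (t - d1) / d2)
  g <- 0.5 + 0.4 * sin(2 * pi * phase)
  cycles <- segment_cycles(make_rec(rbind(g), fs, c(0, d1, d1 + d2)))
  expect_equal(cycles[[1]], cycles[[2]], tolerance = 1e-6)
})

test_that("too few complete cycles raises an eligibility error", {
  rec <- make_rec(matrix(1, 2, 4000), 2000, c(0, 0.9, 1.9))
  expect_error(segment_cycles(rec, min_cycles = 5),
               class = "synkit_eligibility_error")
})

test_that("concatenation scales every channel to unit SD and is invertible", {
  sc <- make_scaled_envelope(3, seed = 21, cfg = noisy_cfg(22))
  emg <- sc$emg
  expect_identical(dim(emg$data), c(8L, 505L))
  expect_equal(unname(apply(emg$data, 1, sd)), rep(1, 8), tolerance = 1e-9)
  raw_env <- simulate_envelope(sc$gt, noisy_cfg(22))
  expect_equal(emg$data * emg$channel_scale, raw_env$data, tolerance = 1e-12)
  already <- concatenate_scale(gait_cycle_matrix(emg$data, 5, 101))
  expect_equal(unname(already$channel_scale), rep(1, 8), tolerance = 1e-9)
})

test_that("a flat channel is rejected by name", {
  data <- rbind(matrix(runif(2 * 202), 2), 0.7)
  rownames(data) <- c("a", "b", "soleus")
  gcm <- gait_cycle_matrix(data, 2, 101)
  expect_error(concatenate_scale(gcm), regexp = "soleus",
               class = "synkit_degenerate_channel_error")
})

test_that("preprocessing recovers the generative envelope from raw EMG", {
  sc <- make_scaled_envelope(3, seed = 31)
  cfg <- noiseless_cfg(131)
  raw <- simulate_raw(simulate_envelope(sc$gt, cfg), cfg)
  rec <- preprocess_emg(raw)
  truth <- concatenate_scale(simulate_envelope(sc$gt, cfg))
  for (m in 1:8) {
    expect_gt(cor(rec$data[m, ], truth$data[m, ]), 0.95)
  }
})
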