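test_that("ground truth has the contracted shape, sign and determinism", {
  gt <- make_ground_truth(8, 3, seed = 1)
  expect_identical(dim(gt$W_true), c(8L, 3L))
  expect_identical(dim(gt$H_true_profile), c(3L, 101L))
  expect_true(all(gt$W_true >= 0) && all(gt$H_true_profile >= 0))
  expect_true(all(colSums(gt$W_true) > 0))
  expect_equal(unname(apply(gt$H_true_profile, 1, max)), rep(1, 3))
  expect_identical(make_ground_truth(8, 3, seed = 1), gt)
  expect_error(make_ground_truth(3, 5, seed = 1), class = "synkit_config_error")
})

test_that("weight columns are pairwise distinct across many draws", {
  for (s in 1:20) {
    gt <- make_ground_truth(8, 4, seed = s)
    cm <- cor(gt$W_true)
    expect_lt(max(cm[upper.tri(cm)]), 0.9)  # signed: near-duplicates excluded
  }
  gt2 <- make_ground_truth(2, 2, seed = 7)
  expect_lt(cor(gt2$W_true)[1, 2], 0.9)
})

test_that("noiseless, jitter-free envelope is the exact factor product", {
  gt <- make_ground_truth(8, 3, seed = 2)
  env <- simulate_envelope(gt, noiseless_cfg(5))
  tiled <- do.call(cbind, rep(list(gt$H_true_profile), 5))
  expect_equal(unname(env$data), unname(gt$W_true %*% tiled), tolerance = 1e-12)
  expect_identical(dim(env$data), c(8L, 505L))
})

test_that("envelope noise has the requested magnitude and preserves sign", {
  ratios <- vapply(1:10, function(s) {
    gt <- make_ground_truth(8, 3, seed = s)
    clean <- simulate_envelope(gt, noiseless_cfg(s))$data
    noisy <- simulate_envelope(gt, noiseless_cfg(s, envelope_noise_sd = 0.1))$data
    expect_true(all(noisy >= 0))
    sd(noisy - clean) / (0.1 * sd(clean))
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < 0.2))
})

test_that("zero perturbation is an exact identity", {
  gt <- make_ground_truth(8, 3, seed = 3)
  gtp <- perturb_ground_truth(gt, 0, 0, seed = 99)
  expect_equal(gtp$W_true, gt$W_true)
  expect_equal(gtp$H_true_profile, gt$H_true_profile)
})

test_that("perturbation size grows with the requested magnitudes", {
  wcor <- function(mag) {
    mean(vapply(1:20, function(s) {
      gt <- make_ground_truth(8, 3, seed = s)
      gtp <- perturb_ground_truth(gt, mag, 0, seed = s + 50)
      mean(diag(cor(gt$W_true, gtp$W_true)))
    }, numeric(1)))
  }
  expect_lt(wcor(0.5), wcor(0.1))
  hrmse <- function(mag) {
    mean(vapply(1:20, function(s) {
      gt <- make_ground_truth(8, 3, seed = s)
      gtp <- perturb_ground_truth(gt, 0, mag, seed = s + 50)
      sqrt(mean((gt$H_true_profile - gtp$H_true_profile)^2))
    }, numeric(1)))
  }
  expect_gt(hrmse(0.5), hrmse(0.1))
})

test_that("raw EMG simulation respects its contracts", {
  gt <- make_ground_truth(4, 2, seed = 4)
  cfg <- noiseless_cfg(6, n_muscles = 4L, n_cycles = 3L)
  env <- simulate_envelope(gt, cfg)
  raw <- simulate_raw(env, cfg)
  expect_length(raw$heel_strikes, cfg$n_cycles + 1L)
  expect_identical(raw$signals, simulate_raw(env, cfg)$signals)
  zero_env <- gait_cycle_matrix(matrix(0, 4, 3 * 101), 3, 101)
  expect_equal(max(abs(simulate_raw(zero_env, cfg)$signals)), 0)
  bad <- cfg
  bad$carrier_band <- c(20, 1500)
  expect_error(simulate_raw(env, bad), class = "synkit_config_error")
})

test_that("a constant envelope yields a steady recovered activation level", {
  cfg <- noiseless_cfg(8, n_muscles = 2L, n_cycles = 5L)
  const_env <- gait_cycle_matrix(matrix(1, 2, 5 * 101), 5, 101)
  raw <- simulate_raw(const_env, cfg)
  env <- emg_envelope(raw)
  mid <- seq(floor(0.2 * ncol(env$signals)), ceiling(0.8 * ncol(env$signals)))
  for (m in 1:2) {
    x <- env$signals[m, mid]
    expect_lt(sd(x) / mean(x), 0.1)
  }
})

test_that("TD-like data are deterministic, well-shaped and richer than rank 2", {
  cfg <- noisy_cfg(11)
  td <- simulate_td_like(cfg, n_syn_td = 5, seed = 11)
  expect_identical(dim(td$data), c(8L, 505L))
  expect_identical(td$data, simulate_td_like(cfg, 5, seed = 11)$data)
  v2 <- extract_synergies(concatenate_scale(td), 2, n_restarts = 3,
                          seed = 1)$fit_vaf
  v5 <- extract_synergies(concatenate_scale(td), 5, n_restarts = 3,
                          seed = 1)$fit_vaf
  expect_gt(v5, v2)
})

test_that("extraction quality degrades monotonically with envelope noise", {
  levels <- c(0, 0.05, 0.1, 0.2, 0.4)
  means <- vapply(levels, function(nl) {
    mean(vapply(1:20, function(s) {
      gt <- make_ground_truth(8, 3, seed = s + 500)
      e <- concatenate_scale(simulate_envelope(
        gt, noiseless_cfg(s * 5 + 2, envelope_noise_sd = nl)))
      extract_synergies(e, 3, n_restarts = 3, seed = s)$fit_vaf
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(levels, means, method = "spearman"), -0.9)
})
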