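test_that("AOA recovers exact activations when a zero-residual solution exists", {
  set.seed(11)
  W <- matrix(runif(8 * 3, 0.1, 1), 8)
  H <- matrix(runif(3 * 30, 0, 1), 3)
  rec <- reconstruct_aoa(W, W %*% H)
  expect_equal(rec$vaf_global, 100, tolerance = 1e-6)
  expect_equal(rec$optimized_factor, H, tolerance = 1e-6)
  expect_equal(rec$rec_emg, rec$fixed_factor %*% rec$optimized_factor,
               tolerance = 1e-9)
})

test_that("the single-synergy AOA solution matches the closed form", {
  rec <- reconstruct_aoa(matrix(c(1, 1), 2), matrix(c(1, 0), 2))
  expect_equal(as.numeric(rec$optimized_factor), 0.5, tolerance = 1e-9)
  expect_equal(rec$vaf_global, 50, tolerance = 1e-9)
})

test_that("AOA and WOA agree with the enumeration oracle on random instances", {
  set.seed(12)
  for (i in 1:12) {
    nm <- sample(2:4, 1); k <- sample(1:2, 1); nc <- sample(3:20, 1)
    W <- matrix(runif(nm * k, 0, 1), nm)
    W[, 1] <- W[, 1] + 0.2
    if (k == 2) W[, 2] <- 0.7 * W[, 1] + 0.3 * W[, 2]  # correlated columns
    V <- matrix(runif(nm * nc), nm)
    rec <- reconstruct_aoa(W, V)
    obj_pkg <- sum((V - rec$rec_emg)^2)
    obj_oracle <- sum(vapply(seq_len(nc), function(j) {
      nnls_enum_oracle(W, V[, j])$obj
    }, numeric(1)))
    expect_equal(obj_pkg, obj_oracle, tolerance = 1e-6)
  }
})

test_that("WOA recovers exact weights and matches its closed form at one synergy", {
  set.seed(13)
  h <- matrix(runif(2 * 101, 0, 1), 2)
  W <- matrix(runif(8 * 2, 0, 1), 8)
  target <- W %*% cbind(h, h, h)
  rec <- reconstruct_woa(h, target)
  expect_equal(unname(rec$optimized_factor), W, tolerance = 1e-6)
  expect_equal(rec$vaf_global, 100, tolerance = 1e-6)
  h1 <- matrix(runif(101, 0.1, 1), 1)
  V <- matrix(runif(3 * 101), 3)
  rec1 <- reconstruct_woa(h1, V)
  expected <- pmax(0, (V %*% t(h1)) / sum(h1^2))
  expect_equal(as.numeric(rec1$optimized_factor), as.numeric(expected),
               tolerance = 1e-9)
})

test_that("WOA is AOA on the transposed problem", {
  set.seed(14)
  V <- matrix(runif(4 * 20), 4)
  h <- matrix(runif(2 * 20, 0, 1), 2)
  woa <- reconstruct_woa(h, V)
  aoa <- reconstruct_aoa(t(h), t(V))
  expect_equal(unname(woa$optimized_factor), t(aoa$optimized_factor),
               tolerance = 1e-9)
})

test_that("reconstructing the fitted data loses almost nothing", {
  sc <- make_scaled_envelope(3, seed = 51)
  fit <- extract_synergies(sc$emg, 3, n_restarts = 5, seed = 2)
  aoa <- reconstruct_aoa(fit$W, sc$emg)
  woa <- reconstruct_woa(fit$H_avg, sc$emg)
  expect_gte(aoa$vaf_global, fit$fit_vaf - 1e-6)
  expect_gte(woa$vaf_global, fit$fit_vaf - 1.0)
})

test_that("collinear fixed factors are solved but flagged non-unique", {
  W <- cbind(c(1, 2, 3), c(2, 4, 6))
  rec <- reconstruct_aoa(W, matrix(runif(3 * 5), 3))
  expect_true(rec$non_unique)
  expect_true(all(rec$optimized_factor >= 0))
})

test_that("unscaled gait-matrix targets are unit-SD scaled before fitting", {
  sc <- make_scaled_envelope(2, seed = 52, cfg = noisy_cfg(53))
  fit <- extract_synergies(sc$emg, 2, n_restarts = 3, seed = 1)
  unscaled <- gait_cycle_matrix(sc$emg$data * sc$emg$channel_scale, 5, 101)
  r1 <- reconstruct_aoa(fit$W, sc$emg)
  r2 <- reconstruct_aoa(fit$W, unscaled)
  expect_equal(r1$vaf_global, r2$vaf_global, tolerance = 1e-9)
})
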