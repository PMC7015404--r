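test_that("leg metrics are exact arithmetic differences", {
  rec <- compute_leg_metrics(94, 86, 74)
  expect_equal(rec$good, 8)
  expect_equal(rec$spec, 12)
  expect_equal(rec$imp, 20)
  expect_identical(rec$spec, rec$imp - rec$good)
  same <- compute_leg_metrics(90, 90, 90)
  expect_identical(c(same$good, same$spec, same$imp), c(0, 0, 0))
  gen <- compute_leg_metrics(94, 86, 74, vaf_pre_gen = 90, vaf_post_gen = 84,
                             vaf_td_gen = 70)
  expect_equal(gen$good_pre_gen, 4)
  expect_equal(gen$good_post_gen, 10)
  expect_equal(gen$spec_pre_gen, 20)
  expect_equal(gen$spec_post_gen, 14)
})

test_that("synergy matching recovers identity, permutations and scalings", {
  set.seed(21)
  W <- matrix(runif(8 * 3, 0, 1), 8)
  m_id <- match_synergies(W, W)
  expect_identical(m_id$pairing, 1:3)
  expect_equal(m_id$correlations, rep(1, 3), tolerance = 1e-12)
  perm <- c(3L, 1L, 2L)
  m_p <- match_synergies(W, W[, perm])
  expect_identical(m_p$pairing, order(perm))
  expect_equal(m_p$correlations, rep(1, 3), tolerance = 1e-12)
  m_s <- match_synergies(W, W %*% diag(c(0.5, 2, 7)))
  expect_identical(m_s$pairing, 1:3)
  expect_equal(m_s$correlations, rep(1, 3), tolerance = 1e-12)
})

test_that("the optimal pairing beats every alternative permutation", {
  set.seed(22)
  for (i in 1:10) {
    A <- matrix(runif(8 * 3), 8)
    B <- matrix(runif(8 * 3), 8)
    m <- match_synergies(A, B)
    total <- sum(m$correlations)
    cm <- cor(A, B)
    for (p in perms_list(3)) {
      expect_gte(total + 1e-12, sum(cm[cbind(1:3, p)]))
    }
  }
})

test_that("matching flags zero-variance columns and rejects shape mismatch", {
  A <- matrix(runif(8 * 2), 8)
  B <- A
  B[, 2] <- 1  # constant column: correlation undefined
  m <- match_synergies(A, B)
  expect_true(any(is.na(m$correlations)))
  expect_error(match_synergies(A, matrix(runif(8 * 3), 8)),
               class = "synkit_data_error")
})

test_that("dW averages pair correlations and rejects all-undefined input", {
  expect_equal(delta_w(c(1, 0.5)), 0.75)
  expect_equal(delta_w(c(1, NA)), 1)
  expect_error(delta_w(c(NA_real_, NA_real_)),
               class = "synkit_undefined_metric_error")
})

test_that("dH is a peak-normalised profile RMSE averaged over pairs", {
  H <- matrix(runif(3 * 101, 0.1, 1), 3)
  expect_equal(delta_h(H, H), 0)
  expect_equal(delta_h(H, 4 * H), 0, tolerance = 1e-12)  # peak-norm invariance
  a <- matrix(c(1, 0), 1)
  b <- matrix(c(0, 1), 1)
  expect_equal(delta_h(a, b), 1)
  expect_error(delta_h(a, matrix(0, 1, 2)),
               class = "synkit_undefined_metric_error")
})

test_that("dW and dH track their generative perturbations", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  res <- vapply(grid, function(mag) {
    per_seed <- vapply(1:20, function(s) {
      gt <- make_ground_truth(8, 3, seed = s + 300)
      gtp <- perturb_ground_truth(gt, mag, mag, seed = s + 400)
      m <- match_synergies(gt$W_true, gtp$W_true)
      c(delta_w(m), delta_h(gt$H_true_profile, gtp$H_true_profile, m$pairing))
    }, numeric(2))
    rowMeans(per_seed)
  }, numeric(2))
  expect_lt(cor(grid, res[1, ], method = "spearman"), -0.8)
  expect_gt(cor(grid, res[2, ], method = "spearman"), 0.8)
})
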