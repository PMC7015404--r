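leg_entry <- function(id, n_syn, seed) {
  sc <- make_scaled_envelope(n_syn, seed = seed, cfg = noisy_cfg(seed + 1000))
  list(id = id, emg = sc$emg, n_syn = n_syn, gt = sc$gt)
}

test_that("legs partition exhaustively and disjointly by synergy count", {
  legs <- list(leg_entry("a", 2, 61), leg_entry("b", 3, 62),
               leg_entry("c", 3, 63), leg_entry("d", 4, 64))
  groups <- group_by_nsyn(legs)
  expect_named(groups, c("nsyn_2", "nsyn_3", "nsyn_4"))
  expect_identical(vapply(groups, function(g) g$n_members, 1L),
                   c(nsyn_2 = 1L, nsyn_3 = 2L, nsyn_4 = 1L))
  expect_setequal(unlist(lapply(groups, `[[`, "member_ids")),
                  c("a", "b", "c", "d"))
  expect_identical(ncol(groups$nsyn_3$concatenated_emg$data), 2L * 505L)
  single <- group_by_nsyn(legs[1])
  expect_equal(single[[1]]$concatenated_emg$data, legs[[1]]$emg$data)
})

test_that("inconsistent muscle counts across members are rejected", {
  l1 <- leg_entry("a", 2, 65)
  l2 <- l1
  l2$emg <- gait_cycle_matrix(l1$emg$data[1:4, ], 5, 101)
  expect_error(group_by_nsyn(list(l1, l2)), class = "synkit_data_error")
})

test_that("generic synergies from copies of one subject match that subject", {
  sc <- make_scaled_envelope(3, seed = 66)
  legs <- lapply(c("L", "R", "X"), function(id) {
    list(id = id, emg = sc$emg, n_syn = 3)
  })
  group <- group_by_nsyn(legs)[[1]]
  gen <- extract_generic(group, seed = 5, n_restarts = 5, tol = 1e-9,
                         max_iter = 5000)
  expect_identical(gen$source, "generic")
  expect_identical(ncol(gen$H_avg), 101L)
  own <- extract_synergies(sc$emg, 3, n_restarts = 5, seed = 6, tol = 1e-9,
                           max_iter = 5000)
  m <- match_synergies(own$W, gen$W)
  expect_true(all(m$correlations > 0.99))
})

test_that("generic reconstruction of the generating member is near perfect", {
  sc <- make_scaled_envelope(2, seed = 67)
  group <- group_by_nsyn(list(list(id = "only", emg = sc$emg, n_syn = 2)))[[1]]
  gen <- extract_generic(group, seed = 7, n_restarts = 5, tol = 1e-9,
                         max_iter = 5000)
  td <- concatenate_scale(simulate_td_like(noisy_cfg(68), 5, seed = 68))
  out <- reconstruct_with_generic(group, gen, pre = list(only = sc$emg),
                                  td = list(td))
  expect_setequal(names(out), c("id", "group", "approach", "source",
                                "target", "vaf"))
  expect_true(all(out$source == "generic"))
  v_pre_aoa <- out$vaf[out$approach == "aoa" & out$target == "pre"]
  expect_gt(v_pre_aoa, 99.9)
  expect_true(all(out$vaf[out$target == "TD"] <
                    out$vaf[out$target == "pre"]))
})

test_that("subject-specific fits explain at least as much as generic ones", {
  diffs <- vapply(1:5, function(s) {
    gt <- make_ground_truth(8, 3, seed = s + 700)
    legs <- lapply(1:3, function(p) {
      gts <- perturb_ground_truth(gt, 0.15, 0.15, seed = s * 31 + p)
      emg <- concatenate_scale(simulate_envelope(gts, noisy_cfg(s * 37 + p)))
      list(id = paste0("s", p), emg = emg, n_syn = 3)
    })
    group <- group_by_nsyn(legs)[[1]]
    gen <- extract_generic(group, seed = s, n_restarts = 5)
    sv <- vapply(legs, function(l) {
      extract_synergies(l$emg, 3, n_restarts = 5, seed = s * 7)$fit_vaf
    }, numeric(1))
    gv <- vapply(legs, function(l) {
      reconstruct_aoa(gen$W, l$emg)$vaf_global
    }, numeric(1))
    mean(sv) - mean(gv)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
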