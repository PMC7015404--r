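all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Match synergies between two weight matrices
#'
#' Pairs each synergy of `w_a` with the most similar synergy of `w_b` by an
#' optimal one-to-one assignment maximising the total Pearson correlation
#' between paired weight columns (exhaustive search, exact for the synergy
#' counts met in gait analysis; greedy above K = 8). A `"greedy"` method is
#' also available.
#'
#' @param w_a,w_b Weight matrices (muscles x K) with equal synergy counts K,
#'   or [synergy_set()] objects.
#' @param method `"optimal"` (default) or `"greedy"`.
#'
#' @return A list with `pairing` (permutation: synergy `k` of `w_a` pairs
#'   with `pairing[k]` of `w_b`) and `correlations` (the K paired Pearson
#'   correlations; `NA` where a weight column has zero variance).
#' @export
match_synergies <- function(w_a, w_b, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (inherits(w_a, "synergy_set")) w_a <- w_a$W
  if (inherits(w_b, "synergy_set")) w_b <- w_b$W
  if (!is.matrix(w_a) || !is.matrix(w_b) || ncol(w_a) != ncol(w_b) ||
      nrow(w_a) != nrow(w_b)) {
    abort("`w_a` and `w_b` must be matrices of identical dimensions.",
          class = "synkit_data_error")
  }
  k <- ncol(w_a)
  cmat <- suppressWarnings(cor(w_a, w_b))  # zero-variance columns -> NA
  score <- ifelse(is.na(cmat), -Inf, cmat)
  if (method == "optimal" && k <= 8L) {
    perms <- all_permutations(k)
    totals <- apply(perms, 1, function(p) sum(score[cbind(seq_len(k), p)]))
    pairing <- perms[which.max(totals), ]
  } else {
    pairing <- integer(k)
    avail <- rep(TRUE, k)
    for (i in seq_len(k)) {
      j <- which.max(ifelse(avail, score[i, ], -Inf))
      pairing[i] <- j
      avail[j] <- FALSE
    }
  }
  list(pairing = as.integer(pairing),
       correlations = cmat[cbind(seq_len(k), pairing)])
}

#' Mean matched-weight correlation (dW)
#'
#' Averages the per-pair Pearson correlations between matched pre- and
#' post-treatment synergy weight vectors, giving one value per leg. Values
#' near 1 mean the muscle co-activation structure was preserved.
#'
#' @param correlations Per-pair correlations from [match_synergies()].
#'
#' @return Scalar mean correlation in `[-1, 1]`.
#' @export
delta_w <- function(correlations) {
  if (is.list(correlations)) correlations <- correlations$correlations
  ok <- !is.na(correlations)
  if (!any(ok)) {
    abort("dW undefined: every matched pair has an undefined correlation.",
          class = "synkit_undefined_metric_error")
  }
  mean(correlations[ok])
}

#' Mean matched activation-profile RMSE (dH)
#'
#' Peak-normalises each averaged activation profile to maximum 1, computes
#' the RMSE between matched pre- and post-treatment profiles, and averages
#' across synergies. Zero means identical activation timing and shape.
#'
#' @param h_a_avg,h_b_avg Averaged profiles (K x samples) or [synergy_set()]s.
#' @param pairing Permutation from [match_synergies()] (row `k` of `h_a_avg`
#'   pairs with row `pairing[k]` of `h_b_avg`). Defaults to the identity.
#' @param normalize `"peak"` (default, maximum scaled to 1) or `"norm"`
#'   (unit Euclidean norm).
#'
#' @return Scalar mean RMSE, `>= 0`.
#' @export
delta_h <- function(h_a_avg, h_b_avg, pairing = NULL,
                    normalize = c("peak", "norm")) {
  normalize <- match.arg(normalize)
  if (inherits(h_a_avg, "synergy_set")) h_a_avg <- h_a_avg$H_avg
  if (inherits(h_b_avg, "synergy_set")) h_b_avg <- h_b_avg$H_avg
  if (is.list(pairing)) pairing <- pairing$pairing
  if (!all(dim(h_a_avg) == dim(h_b_avg))) {
    abort("Profiles must have identical dimensions.",
          class = "synkit_data_error")
  }
  k <- nrow(h_a_avg)
  pairing <- pairing %||% seq_len(k)
  scale_fun <- function(p) {
    s <- if (normalize == "peak") max(p) else sqrt(sum(p^2))
    if (s == 0) {
      abort("dH undefined: an all-zero activation profile cannot be normalized.",
            class = "synkit_undefined_metric_error")
    }
    p / s
  }
  rmse <- vapply(seq_len(k), function(i) {
    a <- scale_fun(h_a_avg[i, ])
    b <- scale_fun(h_b_avg[pairing[i], ])
    sqrt(mean((a - b)^2))
  }, numeric(1))
  mean(rmse)
}

#' Per-leg reconstruction quality metrics
#'
#' Exact arithmetic differences between VAF values (all in percent):
#' `GOOD = VAF_PRE - VAF_POST` (how much worse pre-treatment synergies explain
#' post-treatment data), `SPEC = VAF_POST - VAF_TD` (specificity: how much
#' better they explain the patient's own data than typically-developing data)
#' and `IMP = VAF_PRE - VAF_TD` (pre-treatment impairment proxy), so that
#' `SPEC = IMP - GOOD` identically. When generic-synergy VAFs are supplied the
#' generic variants `GOOD_PRE^gen = VAF_PRE - VAF_PRE^gen`,
#' `GOOD_POST^gen = VAF_PRE - VAF_POST^gen`,
#' `SPEC_PRE^gen = VAF_PRE^gen - VAF_TD^gen` and
#' `SPEC_POST^gen = VAF_POST^gen - VAF_TD^gen` are added.
#'
#' @param vaf_pre Subject-specific extraction VAF, percent.
#' @param vaf_post Reconstruction VAF of post-treatment data, percent.
#' @param vaf_td_mean Mean VAF over the TD reconstructions, percent.
#' @param vaf_pre_gen,vaf_post_gen,vaf_td_gen Optional generic-synergy VAFs.
#'
#' @return One-row tibble with the VAFs and derived metrics.
#' @export
compute_leg_metrics <- function(vaf_pre, vaf_post, vaf_td_mean,
                                vaf_pre_gen = NA_real_,
                                vaf_post_gen = NA_real_,
                                vaf_td_gen = NA_real_) {
  tibble::tibble(
    vaf_pre = vaf_pre, vaf_post = vaf_post, vaf_td = vaf_td_mean,
    good = vaf_pre - vaf_post,
    spec = vaf_post - vaf_td_mean,
    imp = vaf_pre - vaf_td_mean,
    vaf_pre_gen = vaf_pre_gen, vaf_post_gen = vaf_post_gen,
    vaf_td_gen = vaf_td_gen,
    good_pre_gen = vaf_pre - vaf_pre_gen,
    good_post_gen = vaf_pre - vaf_post_gen,
    spec_pre_gen = vaf_pre_gen - vaf_td_gen,
    spec_post_gen = vaf_post_gen - vaf_td_gen)
}
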