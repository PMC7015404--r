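# Exact non-negative least squares min ||A x - b||, x >= 0 (Lawson–Hanson).
nnls_solve <- function(A, b) {
  if (ncol(A) == 1L) {
    # closed form for one synergy: projection clipped at zero
    den <- sum(A^2)
    return(matrix(max(0, sum(A * b) / den), 1, 1))
  }
  matrix(pracma::lsqnonneg(A, b)$x, ncol = 1)
}

new_reconstruction <- function(approach, target_label, optimized_factor,
                               fixed_factor, rec_emg, target, non_unique) {
  structure(
    list(approach = approach, target_label = target_label,
         optimized_factor = optimized_factor, fixed_factor = fixed_factor,
         rec_emg = rec_emg,
         vaf_global = vaf(target, rec_emg),
         vaf_per_muscle = vaf_per_muscle(target, rec_emg),
         non_unique = non_unique),
    class = "synergy_reconstruction")
}

#' @export
print.synergy_reconstruction <- function(x, ...) {
  cat(sprintf("<synergy_reconstruction> %s on '%s': VAF %.1f%%%s\n",
              toupper(x$approach), x$target_label, x$vaf_global,
              if (x$non_unique) " (non-unique solution)" else ""))
  invisible(x)
}

prepare_target <- function(target, scale_target) {
  if (inherits(target, "gait_cycle_matrix")) {
    if (scale_target && !is_scaled(target)) target <- concatenate_scale(target)
    target
  } else {
    check_nonneg_matrix(target, "target")
    target
  }
}

target_data <- function(target) {
  if (inherits(target, "gait_cycle_matrix")) target$data else target
}

#' Activation Optimisation Approach (AOA) reconstruction
#'
#' Keeps the pre-treatment weight vectors fixed and finds the non-negative
#' activations that minimise the summed squared error
#' `sum((target - W_pre %*% H_opt)^2)`. The problem is separable per time
#' column and convex; each column is solved to global optimality by exact
#' non-negative least squares.
#'
#' @param w_pre Fixed weight matrix (muscles x synergies) or a
#'   [synergy_set()] whose `W` is used.
#' @param target Target EMG: a [gait_cycle_matrix()] or non-negative matrix
#'   with the same number of muscle rows. Unscaled gait-cycle matrices are
#'   unit-SD scaled first (same rule as extraction) unless
#'   `scale_target = FALSE`.
#' @param target_label Label stored on the result (e.g. `"post"`, `"TD"`).
#' @param scale_target Apply unit-SD channel scaling to unscaled targets.
#'
#' @return A `synergy_reconstruction` with `H_opt` in `optimized_factor`,
#'   the reconstructed signal, global and per-muscle VAF. Rank-deficient
#'   weight matrices are solved but flagged `non_unique`.
#' @export
reconstruct_aoa <- function(w_pre, target, target_label = "target",
                            scale_target = TRUE) {
  W <- if (inherits(w_pre, "synergy_set")) w_pre$W else w_pre
  check_nonneg_matrix(W, "w_pre")
  if (any(colSums(W) == 0)) {
    abort("`w_pre` has an all-zero synergy column.", class = "synkit_data_error")
  }
  target <- prepare_target(target, scale_target)
  V <- target_data(target)
  if (nrow(V) != nrow(W)) {
    abort("Target muscle count does not match `w_pre`.",
          class = "synkit_data_error")
  }
  H_opt <- matrix(0, ncol(W), ncol(V))
  for (j in seq_len(ncol(V))) H_opt[, j] <- nnls_solve(W, V[, j])
  new_reconstruction("aoa", target_label, H_opt, W, W %*% H_opt, V,
                     non_unique = qr(W)$rank < ncol(W))
}

#' Weight Optimisation Approach (WOA) reconstruction
#'
#' Keeps the averaged pre-treatment activation profiles fixed (tiled across
#' the target's cycles to match its column count) and finds the non-negative
#' weights minimising `sum((target - W_opt %*% H_pre)^2)`. Separable per
#' muscle row and convex; solved exactly per row.
#'
#' @param h_pre_avg Fixed activation profile (synergies x samples-per-cycle)
#'   or a [synergy_set()] whose `H_avg` is used.
#' @param target Target EMG as in [reconstruct_aoa()]; its column count must
#'   be a multiple of the profile length.
#' @param target_label Label stored on the result.
#' @param scale_target Apply unit-SD channel scaling to unscaled targets.
#'
#' @return A `synergy_reconstruction` with `W_opt` in `optimized_factor`.
#' @export
reconstruct_woa <- function(h_pre_avg, target, target_label = "target",
                            scale_target = TRUE) {
  H_avg <- if (inherits(h_pre_avg, "synergy_set")) h_pre_avg$H_avg else h_pre_avg
  check_nonneg_matrix(H_avg, "h_pre_avg")
  if (any(rowSums(H_avg) == 0)) {
    abort("`h_pre_avg` has an all-zero activation row.",
          class = "synkit_data_error")
  }
  target <- prepare_target(target, scale_target)
  V <- target_data(target)
  if (ncol(V) %% ncol(H_avg) != 0L) {
    abort("Target column count must be a multiple of the profile length.",
          class = "synkit_data_error")
  }
  n_rep <- ncol(V) %/% ncol(H_avg)
  H_tiled <- do.call(cbind, rep(list(H_avg), n_rep))
  A <- t(H_tiled)
  W_opt <- matrix(0, nrow(V), nrow(H_avg))
  for (m in seq_len(nrow(V))) W_opt[m, ] <- nnls_solve(A, V[m, ])
  rownames(W_opt) <- rownames(V)
  new_reconstruction("woa", target_label, W_opt, H_tiled, W_opt %*% H_tiled, V,
                     non_unique = qr(A)$rank < ncol(A))
}
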