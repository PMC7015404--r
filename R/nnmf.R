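# One multiplicative-update NNMF run (Lee–Seung, Frobenius loss).
# Returns W, H, the final objective and the per-iteration objective trace.
nnmf_mu <- function(V, k, tol = 1e-6, max_iter = 2000L) {
  eps <- .Machine$double.eps
  nm <- nrow(V); nc <- ncol(V)
  W <- matrix(runif(nm * k, 0.1, 1), nm, k)
  H <- matrix(runif(k * nc, 0.1, 1), k, nc)
  obj <- rep(NA_real_, max_iter)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    R <- V - W %*% H
    obj[it] <- sum(R * R)
    if (is.finite(prev) && abs(prev - obj[it]) <= tol * max(prev, eps)) {
      obj <- obj[seq_len(it)]
      break
    }
    prev <- obj[it]
  }
  list(W = W, H = H, objective = obj[length(obj)], trace = obj[!is.na(obj)])
}

#' Extract muscle synergies by non-negative matrix factorisation
#'
#' Factorises the envelope matrix as `EMG ~ W %*% H` with `W, H >= 0`,
#' minimising the Frobenius reconstruction error by multiplicative updates
#' (Lee–Seung). The best of `n_restarts` seeded random initialisations is
#' kept; synergies are then ordered by the phase of their peak average
#' activation so repeated runs present in a stable order.
#'
#' @param emg A [gait_cycle_matrix()] (or plain non-negative matrix).
#' @param n_syn Number of synergies, `1 <= n_syn <= n_muscles`.
#' @param n_restarts Random restarts (default 10).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param source Provenance tag stored on the result.
#'
#' @return A [synergy_set()] with `fit_vaf` filled in and an
#'   `objective_trace` attribute holding the winning run's objective values.
#' @export
extract_synergies <- function(emg, n_syn, n_restarts = 10L, seed = 1L,
                              tol = 1e-6, max_iter = 2000L,
                              source = "subject-specific") {
  V <- if (inherits(emg, "gait_cycle_matrix")) emg$data else emg
  check_nonneg_matrix(V, "emg")
  n_syn <- stopifnot_scalar_int(n_syn, "n_syn")
  if (n_syn > nrow(V)) {
    abort("`n_syn` cannot exceed the number of muscles.",
          class = "synkit_config_error")
  }
  n_samples <- if (inherits(emg, "gait_cycle_matrix")) emg$n_samples
               else ncol(V)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seeds[r], nnmf_mu(V, n_syn, tol, max_iter))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  H_avg <- average_activation_profile(best$H, n_samples)
  ord <- order(apply(H_avg, 1, which.max))
  W <- best$W[, ord, drop = FALSE]
  H <- best$H[ord, , drop = FALSE]
  H_avg <- H_avg[ord, , drop = FALSE]
  out <- synergy_set(W, H, H_avg, source = source,
                     fit_vaf = vaf(V, W %*% H),
                     channel_names = rownames(V))
  attr(out, "objective_trace") <- best$trace
  out
}

#' Average the activation matrix across cycles
#'
#' Averages the `n_samples`-column time windows of `H` element-wise across
#' all concatenated cycles (and subjects, for generic sets), producing the
#' single activation profile per synergy used by the weight-optimisation
#' reconstruction.
#'
#' @param H Activation matrix (synergies x columns) or a [synergy_set()].
#' @param n_samples Samples per cycle; `ncol(H)` must be a multiple of it.
#'
#' @return Matrix of synergies x `n_samples`.
#' @export
average_activation_profile <- function(H, n_samples) {
  if (inherits(H, "synergy_set")) H <- H$H
  n_samples <- stopifnot_scalar_int(n_samples, "n_samples", min = 1L)
  if (ncol(H) %% n_samples != 0L) {
    abort("`ncol(H)` must be a multiple of `n_samples`.",
          class = "synkit_data_error")
  }
  n_win <- ncol(H) %/% n_samples
  out <- matrix(0, nrow(H), n_samples)
  for (w in seq_len(n_win)) {
    out <- out + H[, ((w - 1) * n_samples + 1):(w * n_samples), drop = FALSE]
  }
  out / n_win
}

#' Select the number of synergies by bootstrap
#'
#' For each candidate rank (scanned upward from 1) the envelope matrix is
#' factorised once on the full data; then `n_boot` resamples of the time
#' columns (with replacement, the same column indices applied to the data and
#' to `H`, keeping `W` fixed) give a distribution of VAF values. The selected
#' rank is the smallest whose `percentile`-th VAF percentile exceeds
#' `vaf_threshold`. If no rank satisfies the criterion the number of muscles
#' is returned with `criterion_met = FALSE`.
#'
#' @param emg A [gait_cycle_matrix()] (or non-negative matrix).
#' @param n_boot Bootstrap replicates per rank (default 500).
#' @param percentile Percentile of the VAF distribution tested (default 95).
#' @param vaf_threshold VAF the percentile must exceed, percent (default 90).
#' @param seed Integer seed covering fits and resampling.
#' @param n_restarts,tol,max_iter Passed to [extract_synergies()].
#' @param max_n_syn Largest rank scanned (default: number of muscles).
#'
#' @return A list of class `nsyn_selection`: `n_syn`, `criterion_met`,
#'   `fits` (one [synergy_set()] per scanned rank) and `diagnostics`
#'   (a tibble with columns `n_syn`, `replicate`, `vaf`).
#' @export
select_n_synergies <- function(emg, n_boot = 500L, percentile = 95,
                               vaf_threshold = 90, seed = 1L,
                               n_restarts = 10L, tol = 1e-6,
                               max_iter = 2000L, max_n_syn = NULL) {
  V <- if (inherits(emg, "gait_cycle_matrix")) emg$data else emg
  check_nonneg_matrix(V, "emg")
  n_boot <- stopifnot_scalar_int(n_boot, "n_boot")
  max_n_syn <- max_n_syn %||% nrow(V)
  seeds <- derive_seeds(seed, 2L * max_n_syn)
  diagnostics <- vector("list", max_n_syn)
  fits <- vector("list", max_n_syn)
  selected <- NA_integer_
  for (k in seq_len(max_n_syn)) {
    fit <- extract_synergies(emg, k, n_restarts = n_restarts,
                             seed = seeds[2L * k - 1L],
                             tol = tol, max_iter = max_iter)
    fits[[k]] <- fit
    R <- fit$W %*% fit$H
    # per-column sufficient statistics make each replicate O(ncol)
    c_er <- colSums(V * R); c_ee <- colSums(V * V); c_rr <- colSums(R * R)
    nc <- ncol(V)
    vafs <- with_seed(seeds[2L * k], {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          idx <- sample.int(nc, nc, replace = TRUE)
          see <- sum(c_ee[idx]); srr <- sum(c_rr[idx])
          if (see > 0 && srr > 0) {
            # clamp away floating-point overshoot above the analytic bound
            return(min(100, sum(c_er[idx])^2 / (see * srr) * 100))
          }
        }
      }, numeric(1))
    })
    diagnostics[[k]] <- tibble::tibble(n_syn = k,
                                       replicate = seq_len(n_boot),
                                       vaf = vafs)
    if (is.na(selected) &&
        quantile(vafs, percentile / 100, names = FALSE) > vaf_threshold) {
      selected <- k
      break
    }
  }
  criterion_met <- !is.na(selected)
  if (!criterion_met) {
    selected <- max_n_syn
    warn("Bootstrap VAF criterion not met at the maximum rank; returning it.")
  }
  structure(
    list(n_syn = selected, criterion_met = criterion_met,
         fits = fits[!vapply(fits, is.null, TRUE)],
         diagnostics = dplyr::bind_rows(diagnostics)),
    class = "nsyn_selection")
}

#' @export
print.nsyn_selection <- function(x, ...) {
  cat(sprintf("<nsyn_selection> n_syn = %d (criterion %s)\n", x$n_syn,
              if (x$criterion_met) "met" else "NOT met"))
  invisible(x)
}
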