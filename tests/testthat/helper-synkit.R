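# Shared fixtures and independent oracles, all built in code.

noiseless_cfg <- function(seed, ...) {
  args <- list(envelope_noise_sd = 0, phase_jitter = 0, amp_jitter = 0,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

noisy_cfg <- function(seed, noise = 0.05, ...) {
  simulation_config(envelope_noise_sd = noise, seed = seed, ...)
}

# Scaled envelope matrix from a fresh ground truth.
make_scaled_envelope <- function(n_syn, seed, cfg = noiseless_cfg(seed + 100)) {
  gt <- make_ground_truth(cfg$n_muscles, n_syn, seed = seed,
                          n_samples = cfg$n_samples)
  list(gt = gt, emg = concatenate_scale(simulate_envelope(gt, cfg)))
}

# Undo the unit-SD channel scaling so fitted weights live on the ground
# truth's amplitude scale before matching.
descale_w <- function(fit, emg) fit$W * emg$channel_scale

# Independent exact NNLS oracle by active-set enumeration: the optimal
# support's restricted least-squares solution is the constrained optimum
# (KKT), so the best sign-feasible restricted solution over all supports is
# the global minimum. Exponential in ncol(A); used only on tiny instances.
nnls_enum_oracle <- function(A, b) {
  k <- ncol(A)
  best <- list(x = rep(0, k), obj = sum(b^2))
  supports <- unlist(lapply(seq_len(k), function(m) {
    asplit(utils::combn(k, m), 2)
  }), recursive = FALSE)
  for (s in supports) {
    As <- A[, s, drop = FALSE]
    coef <- tryCatch(qr.solve(crossprod(As), crossprod(As, b)),
                     error = function(e) NULL)
    if (is.null(coef) || any(coef < -1e-12)) next
    x <- rep(0, k); x[s] <- pmax(0, coef)
    obj <- sum((b - A %*% x)^2)
    if (obj < best$obj) best <- list(x = x, obj = obj)
  }
  best
}

# All permutations of 1..k as a list (iterative construction, independent of
# the package's recursion).
perms_list <- function(k) {
  out <- list(1L)
  for (n in 2:k) {
    out <- unlist(lapply(out, function(p) {
      lapply(seq_len(n), function(pos) append(p, n, after = pos - 1L))
    }), recursive = FALSE)
  }
  out
}
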