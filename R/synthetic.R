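#' Simulation configuration for synthetic EMG
#'
#' Collects the knobs of the synthetic-EMG generator. Defaults match the
#' geometry the analysis pipeline assumes for clinical gait data: 8 muscles,
#' 5 gait cycles time-normalised to 101 samples, raw EMG sampled at 2000 Hz.
#'
#' @param n_muscles Number of EMG channels.
#' @param n_cycles Number of gait cycles per recording.
#' @param n_samples Samples per time-normalised cycle.
#' @param sampling_rate Raw-EMG sampling frequency, Hz.
#' @param cycle_duration_mean Mean stride duration in seconds.
#' @param cycle_duration_cv Coefficient of variation of stride duration.
#' @param envelope_noise_sd Additive envelope noise SD as a fraction of the
#'   envelope's own SD (truncated at zero so envelopes stay non-negative).
#' @param noise_model `"additive"` (default) or `"multiplicative"`.
#' @param phase_jitter SD of the per-cycle phase shift of the activation
#'   profiles, in fractions of a cycle.
#' @param amp_jitter SD of the per-cycle multiplicative amplitude jitter.
#' @param carrier_band Pass band of the surface-EMG interference carrier, Hz.
#' @param dW_mag,dH_mag Default perturbation magnitudes in `[0, 1]` used when
#'   simulating post-treatment data (see [perturb_ground_truth()]).
#' @param seed Integer seed; every generator is a pure function of its seed.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_muscles = 8L, n_cycles = 5L, n_samples = 101L,
                              sampling_rate = 2000, cycle_duration_mean = 1.1,
                              cycle_duration_cv = 0.03,
                              envelope_noise_sd = 0.05,
                              noise_model = c("additive", "multiplicative"),
                              phase_jitter = 0.01, amp_jitter = 0.03,
                              carrier_band = c(20, 450),
                              dW_mag = 0.2, dH_mag = 0.2, seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_muscles = stopifnot_scalar_int(n_muscles, "n_muscles"),
    n_cycles = stopifnot_scalar_int(n_cycles, "n_cycles"),
    n_samples = stopifnot_scalar_int(n_samples, "n_samples", min = 2L),
    sampling_rate = sampling_rate,
    cycle_duration_mean = cycle_duration_mean,
    cycle_duration_cv = cycle_duration_cv,
    envelope_noise_sd = envelope_noise_sd,
    noise_model = noise_model,
    phase_jitter = phase_jitter, amp_jitter = amp_jitter,
    carrier_band = as.numeric(carrier_band),
    dW_mag = dW_mag, dH_mag = dH_mag,
    seed = stopifnot_scalar_int(seed, "seed", min = 0L))
  if (any(c(cfg$envelope_noise_sd < 0, cfg$phase_jitter < 0,
            cfg$amp_jitter < 0, cfg$dW_mag < 0, cfg$dW_mag > 1,
            cfg$dH_mag < 0, cfg$dH_mag > 1))) {
    abort("noise/jitter/perturbation magnitudes must be in their valid ranges.",
          class = "synkit_config_error")
  }
  if (length(cfg$carrier_band) != 2L || cfg$carrier_band[1] <= 0 ||
      cfg$carrier_band[2] <= cfg$carrier_band[1] ||
      cfg$sampling_rate <= 2 * cfg$carrier_band[2]) {
    abort("`carrier_band` must satisfy 0 < low < high < sampling_rate / 2.",
          class = "synkit_config_error")
  }
  structure(cfg, class = "simulation_config")
}

# Circular Gaussian bump in phase (profiles are periodic over the cycle).
circular_bump <- function(phase, centre, width) {
  d <- abs(phase - centre)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / width)^2)
}

#' Generate ground-truth synergies
#'
#' Draws a non-negative weight matrix with distinct columns (pairwise
#' correlation < 0.9) and smooth, peak-normalised activation profiles built
#' from one or two circular Gaussian bumps with peak phases spread across the
#' gait cycle — the burst-like shapes typical of gait EMG.
#'
#' @param n_muscles Number of muscles (rows of `W_true`).
#' @param n_syn Number of synergies, `1 <= n_syn <= n_muscles`.
#' @param seed Integer seed; the output is a pure function of it.
#' @param n_samples Samples per cycle for the activation profiles.
#'
#' @return A list of class `ground_truth_synergies` with elements `W_true`
#'   (n_muscles x n_syn), `H_true_profile` (n_syn x n_samples), `n_syn`, `seed`.
#' @export
make_ground_truth <- function(n_muscles, n_syn, seed, n_samples = 101L) {
  n_muscles <- stopifnot_scalar_int(n_muscles, "n_muscles")
  n_syn <- stopifnot_scalar_int(n_syn, "n_syn")
  if (n_syn > n_muscles) {
    abort("`n_syn` cannot exceed `n_muscles`.", class = "synkit_config_error")
  }
  with_seed(seed, {
    # Each synergy owns a dominant, mostly disjoint muscle group (round-robin
    # assignment) over a weak background — the module-like structure of gait
    # EMG, which also keeps the factorisation essentially unique.
    owner <- rep(seq_len(n_syn), length.out = n_muscles)[sample.int(n_muscles)]
    W <- matrix(0, n_muscles, n_syn)
    for (k in seq_len(n_syn)) {
      for (attempt in 1:100) {
        w <- runif(n_muscles, 0, 0.08)
        w[owner == k] <- runif(sum(owner == k), 0.6, 1)
        w <- w / max(w)
        if (k == 1L || n_muscles == 1L ||
            all(cor(w, W[, seq_len(k - 1L), drop = FALSE]) < 0.9)) break
      }
      W[, k] <- w
    }
    phase <- seq(0, 1, length.out = n_samples)
    H <- matrix(0, n_syn, n_samples)
    centres <- ((seq_len(n_syn) - 0.5) / n_syn + runif(n_syn, -0.04, 0.04)) %% 1
    for (k in seq_len(n_syn)) {
      for (attempt in 1:50) {
        width <- runif(1, 0.04, 0.08)
        prof <- circular_bump(phase, centres[k], width)
        if (attempt <= 25 && runif(1) < 0.4) {  # optional smaller second burst
          off <- runif(1, 0.35, 0.5)
          prof <- prof + runif(1, 0.15, 0.35) *
            circular_bump(phase, (centres[k] + off) %% 1, runif(1, 0.04, 0.07))
        }
        prof <- prof / max(prof)
        prof[prof < 0.005] <- 0  # truncate negligible tails: bursts are
                                 # silent between bursts, keeping the
                                 # factorisation essentially unique
        # bursts must not shadow an earlier synergy's activation pattern:
        # low cosine overlap keeps the factorisation essentially unique
        if (k == 1L) break
        prev <- H[seq_len(k - 1L), , drop = FALSE]
        cosine <- (prev %*% prof) /
          (sqrt(rowSums(prev^2)) * sqrt(sum(prof^2)))
        if (all(cosine < 0.2)) break
      }
      H[k, ] <- prof
    }
    rownames(W) <- default_muscles(n_muscles)
    structure(list(W_true = W, H_true_profile = H, n_syn = n_syn, seed = seed),
              class = "ground_truth_synergies")
  })
}

#' @export
print.ground_truth_synergies <- function(x, ...) {
  cat(sprintf("<ground_truth_synergies> %d muscles x %d synergies (seed %d)\n",
              nrow(x$W_true), x$n_syn, x$seed))
  invisible(x)
}

# Shift a periodic profile by `shift` cycles via linear interpolation.
shift_profile <- function(prof, shift) {
  n <- length(prof)
  phase <- seq(0, 1, length.out = n)
  src <- (phase - shift) %% 1
  # periodic interpolation: continue the cycle around the unit interval,
  # dropping the duplicated endpoints (phase 0 and 1 are the same sample)
  ext_x <- c(phase[-n] - 1, phase, phase[-1] + 1)
  ext_y <- c(prof[-n], prof, prof[-1])
  approx(ext_x, ext_y, xout = src)$y
}

#' Simulate a multi-cycle envelope matrix from ground truth
#'
#' Tiles the ground-truth activation profiles across `cfg$n_cycles` cycles,
#' applying small seeded per-cycle phase and amplitude jitter, forms
#' `envelope = W_true %*% H_tiled`, and adds envelope noise truncated at zero.
#' With zero noise and zero jitter the output equals the exact product.
#'
#' @param gt A [make_ground_truth()] object.
#' @param cfg A [simulation_config()]; `cfg$seed` drives all randomness.
#'
#' @return A [gait_cycle_matrix()] (unscaled).
#' @export
simulate_envelope <- function(gt, cfg) {
  if (nrow(gt$H_true_profile) != gt$n_syn || ncol(gt$W_true) != gt$n_syn ||
      nrow(gt$W_true) != cfg$n_muscles ||
      ncol(gt$H_true_profile) != cfg$n_samples) {
    abort("`gt` and `cfg` are dimensionally inconsistent.",
          class = "synkit_config_error")
  }
  with_seed(cfg$seed, {
    blocks <- vector("list", cfg$n_cycles)
    for (cyc in seq_len(cfg$n_cycles)) {
      Hc <- gt$H_true_profile
      if (cfg$phase_jitter > 0 || cfg$amp_jitter > 0) {
        for (k in seq_len(gt$n_syn)) {
          sh <- rnorm(1, 0, cfg$phase_jitter)
          am <- max(0, 1 + rnorm(1, 0, cfg$amp_jitter))
          Hc[k, ] <- am * shift_profile(Hc[k, ], sh)
        }
      }
      blocks[[cyc]] <- gt$W_true %*% Hc
    }
    env <- do.call(cbind, blocks)
    if (cfg$envelope_noise_sd > 0) {
      if (cfg$noise_model == "additive") {
        env <- env + rnorm(length(env), 0, cfg$envelope_noise_sd * sd(env))
      } else {
        env <- env * (1 + rnorm(length(env), 0, cfg$envelope_noise_sd))
      }
      env[env < 0] <- 0
    }
    gait_cycle_matrix(env, cfg$n_cycles, cfg$n_samples,
                      channel_names = rownames(gt$W_true))
  })
}

#' Simulate raw surface EMG from an envelope
#'
#' Amplitude-modulates a band-limited Gaussian carrier (the standard
#' interference-pattern surrogate for surface EMG) by the time-upsampled
#' envelope, and emits heel-strike times consistent with the seeded cycle
#' durations. Lead-in/lead-out padding (the envelope continued periodically)
#' is added so filtering transients fall outside the analysed cycles.
#'
#' @param env A [gait_cycle_matrix()] envelope (one block per cycle).
#' @param cfg A [simulation_config()].
#'
#' @return An [emg_recording()] whose rectified-and-filtered envelope matches
#'   `env` up to the carrier's smoothing.
#' @export
simulate_raw <- function(env, cfg) {
  fs <- cfg$sampling_rate
  if (cfg$carrier_band[1] <= 0 || cfg$carrier_band[2] >= fs / 2) {
    abort("`carrier_band` must lie inside (0, sampling_rate / 2).",
          class = "synkit_config_error")
  }
  nm <- nrow(env$data)
  nt <- env$n_samples
  with_seed(cfg$seed + 1L, {
    durs <- cfg$cycle_duration_mean *
      pmax(0.5, 1 + cfg$cycle_duration_cv * rnorm(env$n_cycles))
    pad <- 0.5  # seconds of periodic continuation at each end
    hs <- pad + cumsum(c(0, durs))
    total <- sum(durs) + 2 * pad
    n <- ceiling(total * fs)
    t <- (seq_len(n) - 1) / fs
    # map each time point to (cycle, phase), continuing periodically in pads
    cyc_idx <- findInterval(t, hs, rightmost.closed = FALSE)
    cyc_idx[cyc_idx < 1L] <- 1L
    cyc_idx[cyc_idx > env$n_cycles] <- env$n_cycles
    phase <- (t - hs[cyc_idx]) / durs[cyc_idx]
    phase <- phase %% 1
    pgrid <- seq(0, 1, length.out = nt)
    env_t <- matrix(0, nm, n)
    for (m in seq_len(nm)) {
      for (cyc in seq_len(env$n_cycles)) {
        sel <- which(cyc_idx == cyc)
        if (!length(sel)) next
        block <- env$data[m, ((cyc - 1) * nt + 1):(cyc * nt)]
        env_t[m, sel] <- approx(pgrid, block, xout = phase[sel], rule = 2)$y
      }
    }
    bp <- signal::butter(4, cfg$carrier_band / (fs / 2), type = "pass")
    raw <- matrix(0, nm, n)
    for (m in seq_len(nm)) {
      carrier <- signal::filtfilt(bp, rnorm(n))
      ma <- mean(abs(carrier))
      if (ma > 0) carrier <- carrier / ma  # so E|carrier| = 1
      raw[m, ] <- carrier * env_t[m, ]
    }
    rownames(raw) <- env$channel_names
    emg_recording(raw, fs, hs, env$channel_names)
  })
}

#' Perturb ground-truth synergies (post-treatment model)
#'
#' Models the two adaptation mechanisms separately: weight change mixes each
#' column of `W_true` toward a random non-negative direction by fraction
#' `dW_mag`; activation change shifts each profile in phase by up to a quarter
#' cycle scaled by `dH_mag` (random direction per synergy). Zero magnitudes
#' return the input unchanged; perturbation size is monotone in the magnitudes.
#'
#' @param gt A [make_ground_truth()] object.
#' @param dW_mag,dH_mag Perturbation magnitudes in `[0, 1]`.
#' @param seed Integer seed for the perturbation directions.
#'
#' @return A new `ground_truth_synergies` object.
#' @export
perturb_ground_truth <- function(gt, dW_mag, dH_mag, seed) {
  if (dW_mag < 0 || dW_mag > 1 || dH_mag < 0 || dH_mag > 1) {
    abort("Perturbation magnitudes must be in [0, 1].",
          class = "synkit_config_error")
  }
  with_seed(seed, {
    W <- gt$W_true
    if (dW_mag > 0) {
      for (k in seq_len(gt$n_syn)) {
        dir <- stats::rgamma(nrow(W), shape = 1)
        dir <- dir / max(dir)
        W[, k] <- (1 - dW_mag) * W[, k] + dW_mag * dir
        W[, k] <- W[, k] / max(W[, k])
      }
    }
    H <- gt$H_true_profile
    if (dH_mag > 0) {
      sgn <- sample(c(-1, 1), gt$n_syn, replace = TRUE)
      for (k in seq_len(gt$n_syn)) {
        prof <- shift_profile(H[k, ], sgn[k] * 0.25 * dH_mag)
        H[k, ] <- prof / max(prof)
      }
    }
    structure(list(W_true = W, H_true_profile = H, n_syn = gt$n_syn,
                   seed = seed),
              class = "ground_truth_synergies")
  })
}

#' Simulate a typically-developing-like envelope
#'
#' Generates an envelope from an independent, richer ground truth (default 5
#' synergies), so that low-rank patient synergies explain it poorly — giving
#' the specificity statistic a true positive signal.
#'
#' @param cfg A [simulation_config()].
#' @param n_syn_td Number of synergies of the TD-like ground truth.
#' @param seed Integer seed.
#'
#' @return A [gait_cycle_matrix()] (unscaled).
#' @export
simulate_td_like <- function(cfg, n_syn_td = 5L, seed = cfg$seed) {
  seed <- stopifnot_scalar_int(seed, "seed", min = 0L)
  seeds <- derive_seeds(seed, 2L)
  gt <- make_ground_truth(cfg$n_muscles, n_syn_td, seed = seeds[1],
                          n_samples = cfg$n_samples)
  cfg$seed <- seeds[2]
  simulate_envelope(gt, cfg)
}
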