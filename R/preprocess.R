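#' EMG envelope extraction
#'
#' The standard gait-EMG envelope chain, applied per channel in order:
#' high-pass Butterworth (removes motion artefact and baseline drift),
#' demeaning over the whole recording, full-wave rectification, and low-pass
#' Butterworth. Both filters are applied forward-backward (zero phase) so the
#' envelope is not delayed relative to the gait events. Negative values left
#' by low-pass ringing are clipped to zero, since the downstream factorisation
#' requires non-negative input.
#'
#' @param raw An [emg_recording()].
#' @param hp_cutoff High-pass cutoff, Hz (default 40).
#' @param lp_cutoff Low-pass cutoff, Hz (default 6).
#' @param order Butterworth filter order per pass (default 6).
#' @param zero_phase Apply each filter forward-backward (default `TRUE`).
#'
#' @details Filters are designed and applied as cascades of second-order
#'   sections, which stay numerically well-conditioned at cutoffs far below
#'   the Nyquist frequency (a 6th-order 6 Hz low-pass at 2000 Hz is unstable
#'   in single transfer-function form). Zero-phase application uses odd
#'   reflective padding at the signal ends to suppress edge ringing.
#'
#' @return An `emg_recording` with the same geometry whose signals are the
#'   non-negative envelopes.
#' @export
emg_envelope <- function(raw, hp_cutoff = 40, lp_cutoff = 6, order = 6,
                         zero_phase = TRUE) {
  nyq <- raw$sampling_rate / 2
  if (hp_cutoff <= 0 || hp_cutoff >= nyq || lp_cutoff <= 0 || lp_cutoff >= nyq) {
    abort("Filter cutoffs must lie in (0, sampling_rate / 2).",
          class = "synkit_config_error")
  }
  n <- ncol(raw$signals)
  if (n <= 3 * order) {
    abort("Signal too short for the requested filter order.",
          class = "synkit_data_error")
  }
  hp <- butter_sos(order, hp_cutoff / nyq, type = "high")
  lp <- butter_sos(order, lp_cutoff / nyq, type = "low")
  apply_filter <- function(flt, x) {
    if (zero_phase) sos_filtfilt(flt, x) else sos_filter_once(flt, x)
  }
  out <- raw$signals
  for (m in seq_len(nrow(out))) {
    x <- apply_filter(hp, out[m, ])
    x <- abs(x - mean(x))
    x <- apply_filter(lp, x)
    x[x < 0] <- 0
    out[m, ] <- x
  }
  emg_recording(out, raw$sampling_rate, raw$heel_strikes, raw$channel_names)
}

#' Segment an envelope recording into time-normalised gait cycles
#'
#' Each cycle runs from one heel strike (phase 0) to the next (phase 1) and is
#' resampled to exactly `n_samples` points on a uniform phase grid including
#' both endpoints, by linear interpolation (monotone, so non-negativity is
#' preserved).
#'
#' @param env An [emg_recording()] holding envelope signals.
#' @param n_samples Points per normalised cycle (default 101).
#' @param min_cycles Minimum number of complete cycles required; the study's
#'   eligibility rule asks for five. Fewer raises an eligibility error.
#'
#' @return A list of muscles x `n_samples` matrices, one per cycle.
#' @export
segment_cycles <- function(env, n_samples = 101L, min_cycles = 1L) {
  n_samples <- stopifnot_scalar_int(n_samples, "n_samples", min = 2L)
  hs <- env$heel_strikes
  tmax <- (ncol(env$signals) - 1) / env$sampling_rate
  complete <- which(hs[-length(hs)] >= 0 & hs[-1] <= tmax + 1e-9)
  if (length(complete) < min_cycles) {
    abort(sprintf("Recording has %d complete gait cycles; %d required.",
                  length(complete), min_cycles),
          class = "synkit_eligibility_error")
  }
  t_axis <- (seq_len(ncol(env$signals)) - 1) / env$sampling_rate
  lapply(complete, function(i) {
    times <- seq(hs[i], hs[i + 1], length.out = n_samples)
    out <- matrix(0, nrow(env$signals), n_samples,
                  dimnames = list(env$channel_names, NULL))
    for (m in seq_len(nrow(out))) {
      out[m, ] <- approx(t_axis, env$signals[m, ], xout = times, rule = 2)$y
    }
    out[out < 0] <- 0
    out
  })
}

#' Concatenate cycles and scale channels to unit standard deviation
#'
#' Concatenates the normalised cycles along time and divides each channel by
#' its own SD over the concatenated signal, removing amplitude differences
#' caused by electrode placement across sessions and subjects. The divisors
#' are stored so the original amplitudes can be recovered.
#'
#' @param cycles List of muscles x `n_samples` matrices from
#'   [segment_cycles()], or a single unscaled [gait_cycle_matrix()].
#' @param scale Divide each channel by its SD (default `TRUE`).
#'
#' @return A [gait_cycle_matrix()] with `channel_scale` recorded.
#' @export
concatenate_scale <- function(cycles, scale = TRUE) {
  if (inherits(cycles, "gait_cycle_matrix")) {
    gcm <- cycles
  } else {
    if (!length(cycles)) {
      abort("At least one cycle is required.", class = "synkit_data_error")
    }
    nm <- vapply(cycles, nrow, 1L)
    nt <- vapply(cycles, ncol, 1L)
    if (length(unique(nm)) != 1L || length(unique(nt)) != 1L) {
      abort("All cycles must share channel count and sample count.",
            class = "synkit_data_error")
    }
    gcm <- gait_cycle_matrix(do.call(cbind, cycles), length(cycles), nt[1],
                             channel_names = rownames(cycles[[1]]))
  }
  if (!scale) return(gcm)
  sds <- apply(gcm$data, 1, sd)
  if (any(sds < 1e-12)) {
    abort(sprintf("Zero-variance (flat) channel(s): %s.",
                  paste(gcm$channel_names[sds < 1e-12], collapse = ", ")),
          class = "synkit_degenerate_channel_error")
  }
  gait_cycle_matrix(gcm$data / sds, gcm$n_cycles, gcm$n_samples,
                    channel_scale = sds, channel_names = gcm$channel_names)
}

#' Full preprocessing chain: raw recording to scaled envelope matrix
#'
#' Convenience wrapper running [emg_envelope()], [segment_cycles()] and
#' [concatenate_scale()], keeping at most `n_cycles` cycles (the first ones).
#'
#' @param raw An [emg_recording()].
#' @param n_cycles Cycles required and kept (default 5, the eligibility rule).
#' @param n_samples Samples per normalised cycle (default 101).
#' @inheritParams emg_envelope
#'
#' @return A unit-SD [gait_cycle_matrix()].
#' @export
preprocess_emg <- function(raw, n_cycles = 5L, n_samples = 101L,
                           hp_cutoff = 40, lp_cutoff = 6, order = 6,
                           zero_phase = TRUE) {
  env <- emg_envelope(raw, hp_cutoff, lp_cutoff, order, zero_phase)
  cycles <- segment_cycles(env, n_samples, min_cycles = n_cycles)
  concatenate_scale(cycles[seq_len(n_cycles)])
}
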