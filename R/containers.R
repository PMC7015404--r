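#' Multi-channel raw EMG recording
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate, channel
#' names and heel-strike event times. This is the input to the preprocessing
#' chain; consecutive heel strikes delimit gait cycles.
#'
#' @param signals Numeric matrix, channels x samples (arbitrary units).
#' @param sampling_rate Sampling frequency in Hz.
#' @param heel_strikes Strictly increasing heel-strike times in seconds;
#'   at least two are required so that at least one complete cycle exists.
#' @param channel_names Optional character vector of muscle names (one per
#'   row of `signals`).
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, sampling_rate, heel_strikes,
                          channel_names = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    abort("`signals` must be a numeric channels x samples matrix.",
          class = "synkit_data_error")
  }
  if (length(sampling_rate) != 1L || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.",
          class = "synkit_config_error")
  }
  heel_strikes <- as.numeric(heel_strikes)
  if (length(heel_strikes) < 2L || any(diff(heel_strikes) <= 0)) {
    abort("`heel_strikes` must be >= 2 strictly increasing times (seconds).",
          class = "synkit_data_error")
  }
  channel_names <- channel_names %||% rownames(signals) %||%
    default_muscles(nrow(signals))
  if (length(channel_names) != nrow(signals)) {
    abort("`channel_names` length must equal the number of channels.",
          class = "synkit_data_error")
  }
  rownames(signals) <- channel_names
  structure(
    list(signals = signals, sampling_rate = sampling_rate,
         heel_strikes = heel_strikes, channel_names = channel_names),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz, %d heel strikes (%d cycles)\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate,
              length(x$heel_strikes), length(x$heel_strikes) - 1L))
  invisible(x)
}

#' Gait-cycle envelope matrix
#'
#' The concatenated, time-normalised envelope matrix on which synergies are
#' computed: `n_muscles` rows and `n_cycles * n_samples` columns. When
#' `channel_scale` has been applied every row has unit standard deviation.
#'
#' @param data Non-negative numeric matrix, muscles x (cycles * samples).
#' @param n_cycles Number of concatenated gait cycles.
#' @param n_samples Samples per time-normalised cycle (101 by convention).
#' @param channel_scale Per-channel divisor already applied (original SDs),
#'   or `NULL` when the matrix is unscaled.
#' @param channel_names Muscle names, one per row.
#'
#' @return An object of class `gait_cycle_matrix`.
#' @export
gait_cycle_matrix <- function(data, n_cycles, n_samples,
                              channel_scale = NULL, channel_names = NULL) {
  check_nonneg_matrix(data, "data")
  n_cycles <- stopifnot_scalar_int(n_cycles, "n_cycles")
  n_samples <- stopifnot_scalar_int(n_samples, "n_samples", min = 2L)
  if (ncol(data) != n_cycles * n_samples) {
    abort(sprintf("`data` has %d columns; expected n_cycles * n_samples = %d.",
                  ncol(data), n_cycles * n_samples),
          class = "synkit_data_error")
  }
  channel_names <- channel_names %||% rownames(data) %||%
    default_muscles(nrow(data))
  rownames(data) <- channel_names
  if (!is.null(channel_scale) && length(channel_scale) != nrow(data)) {
    abort("`channel_scale` must have one entry per channel.",
          class = "synkit_data_error")
  }
  structure(
    list(data = data, n_cycles = n_cycles, n_samples = n_samples,
         channel_scale = channel_scale, channel_names = channel_names),
    class = "gait_cycle_matrix")
}

is_scaled <- function(x) !is.null(x$channel_scale)

#' @export
print.gait_cycle_matrix <- function(x, ...) {
  cat(sprintf("<gait_cycle_matrix> %d muscles x (%d cycles x %d samples)%s\n",
              nrow(x$data), x$n_cycles, x$n_samples,
              if (is_scaled(x)) ", unit-SD scaled" else ""))
  invisible(x)
}

#' Muscle synergy set
#'
#' Holds the non-negative factors of an EMG envelope matrix: weights `W`
#' (muscles x synergies), activations `H` (synergies x concatenated time
#' samples), and the cycle-averaged activation profile `H_avg`
#' (synergies x samples-per-cycle).
#'
#' @param W Non-negative weight matrix, muscles x synergies.
#' @param H Non-negative activation matrix, synergies x time columns.
#' @param H_avg Cycle-averaged activation profile, synergies x `n_samples`.
#' @param source One of `"subject-specific"`, `"generic"`, `"ground-truth"`.
#' @param fit_vaf Global VAF (percent) of `W %*% H` against the fitted data,
#'   or `NA` when not applicable.
#' @param channel_names Muscle names for the rows of `W`.
#'
#' @return An object of class `synergy_set`.
#' @export
synergy_set <- function(W, H, H_avg, source = "subject-specific",
                        fit_vaf = NA_real_, channel_names = NULL) {
  check_nonneg_matrix(W, "W")
  check_nonneg_matrix(H, "H")
  check_nonneg_matrix(H_avg, "H_avg")
  if (ncol(W) != nrow(H) || nrow(H_avg) != ncol(W)) {
    abort("W, H and H_avg synergy dimensions disagree.",
          class = "synkit_data_error")
  }
  source <- match.arg(source, c("subject-specific", "generic", "ground-truth"))
  channel_names <- channel_names %||% rownames(W) %||%
    default_muscles(nrow(W))
  rownames(W) <- channel_names
  structure(
    list(W = W, H = H, H_avg = H_avg, n_syn = ncol(W), source = source,
         fit_vaf = fit_vaf, channel_names = channel_names),
    class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> %d synergies x %d muscles (%s)%s\n",
              x$n_syn, nrow(x$W), x$source,
              if (is.finite(x$fit_vaf)) sprintf(", fit VAF %.1f%%", x$fit_vaf) else ""))
  invisible(x)
}
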