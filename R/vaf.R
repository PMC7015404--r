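#' Variance accounted for (VAF)
#'
#' The squared uncentred correlation between the vectorised experimental and
#' reconstructed matrices, times 100:
#' \deqn{VAF = \frac{(\sum_{t}\sum_{m} EMG^{xp}_{m,t} \, recEMG_{m,t})^2}
#'   {\sum_{t}\sum_{m} (EMG^{xp}_{m,t})^2 \; \sum_{t}\sum_{m} (recEMG_{m,t})^2}
#'   \times 100}
#' Scale-invariant in either argument and bounded in \[0, 100\] by
#' Cauchy–Schwarz.
#'
#' @param emg_xp Experimental matrix (or vector).
#' @param rec_emg Reconstructed matrix of the same shape.
#'
#' @return VAF in percent.
#' @export
vaf <- function(emg_xp, rec_emg) {
  emg_xp <- as.numeric(emg_xp); rec_emg <- as.numeric(rec_emg)
  if (length(emg_xp) != length(rec_emg)) {
    abort("`emg_xp` and `rec_emg` must have the same shape.",
          class = "synkit_data_error")
  }
  den <- sum(emg_xp^2) * sum(rec_emg^2)
  if (den == 0) {
    abort("VAF undefined: one of the signals is identically zero.",
          class = "synkit_undefined_vaf_error")
  }
  sum(emg_xp * rec_emg)^2 / den * 100
}

#' Per-muscle VAF
#'
#' Applies the [vaf()] formula to each muscle row independently, separating
#' the contributions of the individual muscles to the global VAF. Rows whose
#' experimental or reconstructed signal is identically zero yield `NA`
#' (undefined, never reported as zero).
#'
#' @param emg_xp Experimental matrix, muscles x time.
#' @param rec_emg Reconstructed matrix of the same shape.
#'
#' @return Named numeric vector of VAF percentages, one per muscle.
#' @export
vaf_per_muscle <- function(emg_xp, rec_emg) {
  if (!is.matrix(emg_xp) || !all(dim(emg_xp) == dim(rec_emg))) {
    abort("`emg_xp` and `rec_emg` must be matrices of identical shape.",
          class = "synkit_data_error")
  }
  out <- vapply(seq_len(nrow(emg_xp)), function(m) {
    den <- sum(emg_xp[m, ]^2) * sum(rec_emg[m, ]^2)
    if (den == 0) NA_real_ else sum(emg_xp[m, ] * rec_emg[m, ])^2 / den * 100
  }, numeric(1))
  setNames(out, rownames(emg_xp))
}
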