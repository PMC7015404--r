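#' Write / read a raw EMG recording as CSV
#'
#' The recording goes to two plain-text files: `<stem>.csv` with a `time_s`
#' column plus one column per muscle, and `<stem>_events.csv` with columns
#' `cycle_index,heel_strike_s`.
#'
#' @param rec An [emg_recording()].
#' @param stem Output path stem (no extension).
#' @return `write_recording` returns the two paths invisibly;
#'   `read_recording` an `emg_recording`.
#' @export
write_recording <- function(rec, stem) {
  sig_path <- paste0(stem, ".csv")
  ev_path <- paste0(stem, "_events.csv")
  df <- data.frame(time_s = (seq_len(ncol(rec$signals)) - 1) / rec$sampling_rate,
                   t(rec$signals), check.names = FALSE)
  utils::write.csv(df, sig_path, row.names = FALSE)
  utils::write.csv(data.frame(cycle_index = seq_along(rec$heel_strikes) - 1L,
                              heel_strike_s = rec$heel_strikes),
                   ev_path, row.names = FALSE)
  invisible(c(sig_path, ev_path))
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  ev <- utils::read.csv(paste0(stem, "_events.csv"))
  fs <- 1 / stats::median(diff(df$time_s))
  sig <- t(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]))
  emg_recording(sig, round(fs, 6), ev$heel_strike_s,
                channel_names = rownames(sig))
}

#' Write / read a gait-cycle envelope matrix as CSV
#'
#' A muscles x columns CSV preceded by a 3-line `#`-prefixed metadata header
#' recording `n_cycles`, `n_samples` and the applied channel scaling.
#'
#' @param gcm A [gait_cycle_matrix()].
#' @param path Output file.
#' @return `write_gait_matrix` returns `path` invisibly; `read_gait_matrix`
#'   a `gait_cycle_matrix`.
#' @export
write_gait_matrix <- function(gcm, path) {
  scale_line <- if (is_scaled(gcm)) {
    paste(format(gcm$channel_scale, digits = 17), collapse = ",")
  } else "none"
  header <- c(sprintf("# n_cycles: %d", gcm$n_cycles),
              sprintf("# n_samples: %d", gcm$n_samples),
              sprintf("# scaling: %s", scale_line))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(data.frame(muscle = gcm$channel_names, gcm$data,
                                check.names = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_matrix
#' @export
read_gait_matrix <- function(path) {
  header <- readLines(path, n = 3L)
  meta <- function(i) sub("^# [a-z_]+: ", "", header[i])
  df <- utils::read.csv(path, skip = 3L, header = FALSE)
  data <- as.matrix(df[, -1, drop = FALSE])
  dimnames(data) <- list(df[[1]], NULL)
  scaling <- meta(3)
  channel_scale <- if (identical(scaling, "none")) NULL
                   else setNames(as.numeric(strsplit(scaling, ",")[[1]]),
                                 df[[1]])
  gait_cycle_matrix(data, as.integer(meta(1)), as.integer(meta(2)),
                    channel_scale = channel_scale, channel_names = df[[1]])
}

#' Write / read ground-truth synergies as JSON
#'
#' @param gt A [make_ground_truth()] object.
#' @param path Output file.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   a `ground_truth_synergies`.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(
    list(W_true = gt$W_true, H_true_profile = gt$H_true_profile,
         n_syn = gt$n_syn, seed = gt$seed,
         muscles = rownames(gt$W_true)),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(x$W_true)
  rownames(W) <- x$muscles
  structure(list(W_true = W, H_true_profile = as.matrix(x$H_true_profile),
                 n_syn = as.integer(x$n_syn), seed = as.integer(x$seed)),
            class = "ground_truth_synergies")
}

#' Write a synergy set to JSON plus CSV factor matrices
#'
#' `<stem>.json` holds the full set; `<stem>_W.csv`, `<stem>_H.csv` and
#' `<stem>_Havg.csv` the individual factors for spreadsheet consumption.
#'
#' @param syn A [synergy_set()].
#' @param stem Output path stem.
#' @return The JSON path, invisibly.
#' @export
write_synergy_set <- function(syn, stem) {
  jsonlite::write_json(
    list(W = syn$W, H = syn$H, H_avg = syn$H_avg, n_syn = syn$n_syn,
         source = syn$source, fit_vaf = syn$fit_vaf,
         muscles = syn$channel_names),
    paste0(stem, ".json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor")
  utils::write.csv(data.frame(muscle = syn$channel_names, syn$W),
                   paste0(stem, "_W.csv"), row.names = FALSE)
  utils::write.csv(syn$H, paste0(stem, "_H.csv"), row.names = FALSE)
  utils::write.csv(syn$H_avg, paste0(stem, "_Havg.csv"), row.names = FALSE)
  invisible(paste0(stem, ".json"))
}

#' Write a cohort metrics report
#'
#' The tidy per-leg table goes to `<stem>.csv` (one row per leg x approach)
#' and group-level means/SDs to `<stem>_summary.json`.
#'
#' @param report A `synergy_report` from [run_cohort()].
#' @param stem Output path stem.
#' @return The CSV path, invisibly.
#' @export
write_report <- function(report, stem) {
  utils::write.csv(report$metrics, paste0(stem, ".csv"), row.names = FALSE)
  summ <- report$metrics |>
    dplyr::group_by(.data$n_syn, .data$approach) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("vaf_pre", "vaf_post", "vaf_td", "good", "spec", "imp",
                      "d_w", "d_h")),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))),
      n_legs = dplyr::n(), .groups = "drop")
  jsonlite::write_json(summ, paste0(stem, "_summary.json"),
                       digits = NA, dataframe = "rows")
  invisible(paste0(stem, ".csv"))
}
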