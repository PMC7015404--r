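#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a synergy set into a long tibble
#'
#' @param x A [synergy_set()].
#' @param matrix Which factor to tidy: `"W"` (weights, one row per
#'   muscle x synergy) or `"H_avg"` (averaged activation profile, one row per
#'   synergy x phase sample).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.synergy_set <- function(x, matrix = c("W", "H_avg"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::tibble(
      muscle = rep(x$channel_names, times = x$n_syn),
      synergy = rep(seq_len(x$n_syn), each = nrow(x$W)),
      weight = as.numeric(x$W))
  } else {
    nt <- ncol(x$H_avg)
    tibble::tibble(
      synergy = rep(seq_len(x$n_syn), times = nt),
      phase = rep(seq(0, 1, length.out = nt), each = x$n_syn),
      activation = as.numeric(x$H_avg))
  }
}

#' @rdname tidy.synergy_set
#' @export
glance.synergy_set <- function(x, ...) {
  tibble::tibble(n_syn = x$n_syn, n_muscles = nrow(x$W),
                 source = x$source, fit_vaf = x$fit_vaf)
}

#' Tidy a reconstruction result
#'
#' @param x A `synergy_reconstruction`.
#' @param ... Unused.
#' @return One row per muscle with its VAF; `glance` gives the global fit.
#' @export
tidy.synergy_reconstruction <- function(x, ...) {
  tibble::tibble(
    muscle = names(x$vaf_per_muscle) %||%
      paste0("m", seq_along(x$vaf_per_muscle)),
    approach = x$approach, target = x$target_label,
    vaf = unname(x$vaf_per_muscle))
}

#' @rdname tidy.synergy_reconstruction
#' @export
glance.synergy_reconstruction <- function(x, ...) {
  tibble::tibble(approach = x$approach, target = x$target_label,
                 vaf_global = x$vaf_global, non_unique = x$non_unique)
}

#' Tidy bootstrap rank-selection diagnostics
#'
#' @param x An `nsyn_selection` from [select_n_synergies()].
#' @param ... Unused.
#' @return The per-replicate VAF tibble (`n_syn`, `replicate`, `vaf`).
#' @export
tidy.nsyn_selection <- function(x, ...) x$diagnostics

#' @rdname tidy.nsyn_selection
#' @export
glance.nsyn_selection <- function(x, ...) {
  tibble::tibble(n_syn = x$n_syn, criterion_met = x$criterion_met)
}

#' Plot synergy weights and averaged activation profiles
#'
#' Weights as per-synergy bar panels, activations as phase curves — the
#' standard presentation for gait synergies.
#'
#' @param object A [synergy_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_set <- function(object, ...) {
  w <- tidy(object, "W")
  ggplot2::ggplot(w, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~synergy, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot averaged activation profiles over the gait cycle
#'
#' @param syn A [synergy_set()].
#' @return A ggplot object.
#' @export
plot_activations <- function(syn) {
  h <- tidy(syn, "H_avg")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$phase, y = .data$activation,
                                  colour = factor(.data$synergy))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "gait-cycle phase", y = "activation",
                  colour = "synergy") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap VAF distributions per candidate synergy count
#'
#' @param object An `nsyn_selection`.
#' @param vaf_threshold Reference line (percent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nsyn_selection <- function(object, vaf_threshold = 90, ...) {
  ggplot2::ggplot(object$diagnostics,
                  ggplot2::aes(x = factor(.data$n_syn), y = .data$vaf)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = vaf_threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "number of synergies", y = "bootstrap VAF (%)") +
    ggplot2::theme_minimal()
}

#' Plot cohort metrics by approach and synergy-count group
#'
#' @param object A `synergy_report` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_report <- function(object, ...) {
  long <- object$metrics |>
    dplyr::select(dplyr::all_of(c("id", "n_syn", "approach",
                                  "vaf_pre", "vaf_post", "vaf_td"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("vaf_pre", "vaf_post", "vaf_td")),
                        names_to = "condition", values_to = "vaf") |>
    dplyr::mutate(condition = factor(.data$condition,
                                     c("vaf_pre", "vaf_post", "vaf_td"),
                                     c("PRE", "POST", "TD")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$vaf,
                                     fill = .data$condition)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_grid(toupper(approach) ~ n_syn,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "VAF (%)") +
    ggplot2::theme_minimal()
}
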