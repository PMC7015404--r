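#' Analysis pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline, with the defaults the
#' analysis is defined with: 40/6 Hz zero-phase Butterworth envelope chain,
#' 101 samples per stride, 5 cycles, 500 bootstrap replicates with the
#' 95th-percentile-above-90% rank criterion, 10 NNMF restarts.
#'
#' @param n_cycles,n_samples Stride geometry.
#' @param hp_cutoff,lp_cutoff,filter_order,zero_phase Envelope chain.
#' @param n_restarts,tol,max_iter NNMF fitting.
#' @param n_boot,percentile,vaf_threshold Bootstrap rank selection.
#' @param scale_target Unit-SD scale reconstruction targets.
#' @param matching `"optimal"` or `"greedy"` synergy matching.
#' @param dh_normalize `"peak"` or `"norm"` profile normalisation for dH.
#' @param seed Master seed; every stage derives its own stream from it.
#'
#' @return A list of class `synergy_config`.
#' @export
synergy_config <- function(n_cycles = 5L, n_samples = 101L,
                           hp_cutoff = 40, lp_cutoff = 6,
                           filter_order = 6, zero_phase = TRUE,
                           n_restarts = 10L, tol = 1e-6, max_iter = 2000L,
                           n_boot = 500L, percentile = 95, vaf_threshold = 90,
                           scale_target = TRUE,
                           matching = c("optimal", "greedy"),
                           dh_normalize = c("peak", "norm"), seed = 1L) {
  structure(
    list(n_cycles = stopifnot_scalar_int(n_cycles, "n_cycles"),
         n_samples = stopifnot_scalar_int(n_samples, "n_samples", min = 2L),
         hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
         filter_order = filter_order, zero_phase = isTRUE(zero_phase),
         n_restarts = stopifnot_scalar_int(n_restarts, "n_restarts"),
         tol = tol, max_iter = stopifnot_scalar_int(max_iter, "max_iter"),
         n_boot = stopifnot_scalar_int(n_boot, "n_boot"),
         percentile = percentile, vaf_threshold = vaf_threshold,
         scale_target = isTRUE(scale_target),
         matching = match.arg(matching),
         dh_normalize = match.arg(dh_normalize),
         seed = stopifnot_scalar_int(seed, "seed", min = 0L)),
    class = "synergy_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config A [synergy_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `synergy_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synergy_config, vals)
}

#' Simulate a full synthetic cohort
#'
#' Generates, per leg, a ground truth with the group's synergy count, a
#' pre-treatment recording, and a post-treatment recording from the perturbed
#' ground truth ([perturb_ground_truth()]), plus a set of
#' typically-developing-like recordings from independent richer ground
#' truths. Treatment labels (alternating botox/semls) are carried as metadata
#' only.
#'
#' @param groups Named integer vector: legs per synergy-count group, e.g.
#'   `c("2" = 3, "3" = 5, "4" = 3)`.
#' @param n_td Number of TD-like datasets (default 7).
#' @param cfg A [simulation_config()] template; its `dW_mag`/`dH_mag` set the
#'   post-treatment perturbation and `n_syn_td` the TD richness.
#' @param n_syn_td Synergy count of the TD-like ground truths (default 5).
#' @param level `"raw"` (default) emits [emg_recording()]s for the full
#'   chain; `"envelope"` emits [gait_cycle_matrix()] envelopes directly.
#' @param seed Master seed.
#'
#' @return A list of class `synthetic_cohort` with `legs` (each holding
#'   `id`, `n_syn_true`, `treatment`, `gt_pre`, `gt_post`, `pre`, `post`),
#'   `td` (list of TD datasets), `level` and `seed`.
#' @export
simulate_cohort <- function(groups, n_td = 7L, cfg = simulation_config(),
                            n_syn_td = 5L, level = c("raw", "envelope"),
                            seed = 1L) {
  level <- match.arg(level)
  ks <- as.integer(names(groups))
  if (any(is.na(ks)) || any(groups < 0)) {
    abort("`groups` must be a named vector: legs per synergy count.",
          class = "synkit_config_error")
  }
  n_legs <- sum(groups)
  seeds <- derive_seeds(seed, 3L * n_legs + n_td)
  legs <- list()
  idx <- 0L
  for (g in seq_along(groups)) {
    for (i in seq_len(groups[g])) {
      idx <- idx + 1L
      gt_pre <- make_ground_truth(cfg$n_muscles, ks[g], seed = seeds[3L * idx - 2L],
                                  n_samples = cfg$n_samples)
      gt_post <- perturb_ground_truth(gt_pre, cfg$dW_mag, cfg$dH_mag,
                                      seed = seeds[3L * idx - 1L])
      cfg_pre <- cfg; cfg_pre$seed <- seeds[3L * idx]
      cfg_post <- cfg; cfg_post$seed <- seeds[3L * idx] + 1L
      pre <- simulate_envelope(gt_pre, cfg_pre)
      post <- simulate_envelope(gt_post, cfg_post)
      if (level == "raw") {
        pre <- simulate_raw(pre, cfg_pre)
        post <- simulate_raw(post, cfg_post)
      }
      legs[[idx]] <- list(id = sprintf("leg_%02d", idx), n_syn_true = ks[g],
                          treatment = if (idx %% 2L) "botox" else "semls",
                          gt_pre = gt_pre, gt_post = gt_post,
                          pre = pre, post = post)
    }
  }
  td <- lapply(seq_len(n_td), function(i) {
    x <- simulate_td_like(cfg, n_syn_td = n_syn_td,
                          seed = seeds[3L * n_legs + i])
    if (level == "raw") {
      cfg_td <- cfg; cfg_td$seed <- seeds[3L * n_legs + i]
      x <- simulate_raw(x, cfg_td)
    }
    x
  })
  structure(list(legs = legs, td = td, level = level, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d legs x 2 conditions + %d TD datasets (%s level, seed %d)\n",
              length(x$legs), length(x$td), x$level, x$seed))
  invisible(x)
}

as_scaled_gcm <- function(x, config) {
  if (inherits(x, "emg_recording")) {
    preprocess_emg(x, n_cycles = config$n_cycles,
                   n_samples = config$n_samples,
                   hp_cutoff = config$hp_cutoff, lp_cutoff = config$lp_cutoff,
                   order = config$filter_order,
                   zero_phase = config$zero_phase)
  } else if (is_scaled(x)) {
    x
  } else {
    concatenate_scale(x)
  }
}

#' Run the full synergy analysis on a cohort
#'
#' Executes the study-shaped workflow end to end: preprocessing and
#' eligibility checking, bootstrap selection of the synergy count on
#' pre-treatment data, subject-specific NNMF, AOA/WOA reconstruction of the
#' pre-treatment, post-treatment and TD data, a post-treatment refit at the
#' pre-treatment synergy count for dW/dH, grouping by synergy count, generic
#' synergy extraction and generic reconstructions, and the derived metrics.
#' Ineligible or failing legs are skipped with a logged reason; a run is
#' reproducible given (cohort, config).
#'
#' @param cohort A [simulate_cohort()] object, or a list with `legs` (each
#'   with `id`, `pre`, `post` recordings or envelope matrices) and `td`.
#' @param config A [synergy_config()].
#' @param fixed_n_syn Optional integer: skip bootstrap selection and use this
#'   synergy count for every leg (`NULL`, the default, selects per leg).
#'
#' @return A list of class `synergy_report`: `metrics` (tibble, one row per
#'   leg x approach, with VAFs, GOOD/SPEC/IMP, generic variants, dW, dH),
#'   `per_muscle` (tibble of per-muscle VAFs), `fits`, `generic`, `skipped`.
#' @export
run_cohort <- function(cohort, config = synergy_config(),
                       fixed_n_syn = NULL) {
  seeds <- derive_seeds(config$seed, 4L * length(cohort$legs) + 10L)
  td_gcm <- lapply(cohort$td, as_scaled_gcm, config = config)
  skipped <- list()
  analysed <- list()
  for (i in seq_along(cohort$legs)) {
    leg <- cohort$legs[[i]]
    res <- tryCatch({
      pre <- as_scaled_gcm(leg$pre, config)
      post <- as_scaled_gcm(leg$post, config)
      if (is.null(fixed_n_syn)) {
        sel <- select_n_synergies(
          pre, n_boot = config$n_boot, percentile = config$percentile,
          vaf_threshold = config$vaf_threshold, seed = seeds[4L * i - 3L],
          n_restarts = config$n_restarts, tol = config$tol,
          max_iter = config$max_iter)
        n_syn <- sel$n_syn
        fit_pre <- sel$fits[[n_syn]]
      } else {
        n_syn <- as.integer(fixed_n_syn)
        fit_pre <- extract_synergies(
          pre, n_syn, n_restarts = config$n_restarts,
          seed = seeds[4L * i - 3L], tol = config$tol,
          max_iter = config$max_iter)
      }
      fit_post <- extract_synergies(
        post, n_syn, n_restarts = config$n_restarts,
        seed = seeds[4L * i - 2L], tol = config$tol,
        max_iter = config$max_iter)
      m <- match_synergies(fit_pre$W, fit_post$W, method = config$matching)
      list(id = leg$id, n_syn = n_syn, treatment = leg$treatment,
           pre = pre, post = post, fit_pre = fit_pre, fit_post = fit_post,
           d_w = delta_w(m$correlations),
           d_h = delta_h(fit_pre$H_avg, fit_post$H_avg, m$pairing,
                         normalize = config$dh_normalize))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(id = leg$id, reason = conditionMessage(res))
    } else {
      analysed[[length(analysed) + 1L]] <- res
    }
  }
  if (!length(analysed)) {
    abort("No eligible legs.", class = "synkit_data_error")
  }
  # generic synergies per synergy-count group
  groups <- group_by_nsyn(lapply(analysed, function(a) {
    list(id = a$id, emg = a$pre, n_syn = a$n_syn)
  }))
  generic <- list()
  generic_vafs <- list()
  for (g in seq_along(groups)) {
    gen <- extract_generic(groups[[g]], seed = seeds[4L * length(cohort$legs) + g],
                           n_restarts = config$n_restarts, tol = config$tol,
                           max_iter = config$max_iter)
    generic[[names(groups)[g]]] <- gen
    pre_l <- setNames(lapply(analysed, `[[`, "pre"),
                      vapply(analysed, `[[`, "", "id"))
    post_l <- setNames(lapply(analysed, `[[`, "post"),
                       vapply(analysed, `[[`, "", "id"))
    generic_vafs[[g]] <- reconstruct_with_generic(groups[[g]], gen,
                                                  pre = pre_l, post = post_l,
                                                  td = td_gcm)
  }
  generic_vafs <- dplyr::bind_rows(generic_vafs)
  # per-leg subject-specific reconstructions and metrics
  metric_rows <- list()
  muscle_rows <- list()
  for (a in analysed) {
    recs <- list(
      aoa = list(post = reconstruct_aoa(a$fit_pre$W, a$post, "post"),
                 td = lapply(td_gcm, function(x)
                   reconstruct_aoa(a$fit_pre$W, x, "TD"))),
      woa = list(post = reconstruct_woa(a$fit_pre$H_avg, a$post, "post"),
                 td = lapply(td_gcm, function(x)
                   reconstruct_woa(a$fit_pre$H_avg, x, "TD"))))
    for (app in c("aoa", "woa")) {
      vaf_td <- if (length(td_gcm)) {
        mean(vapply(recs[[app]]$td, `[[`, numeric(1), "vaf_global"))
      } else NA_real_
      gv <- function(tgt) {
        v <- generic_vafs$vaf[generic_vafs$id == a$id &
                                generic_vafs$approach == app &
                                generic_vafs$target == tgt]
        if (length(v)) v[1] else NA_real_
      }
      row <- compute_leg_metrics(
        vaf_pre = a$fit_pre$fit_vaf,
        vaf_post = recs[[app]]$post$vaf_global,
        vaf_td_mean = vaf_td,
        vaf_pre_gen = gv("pre"), vaf_post_gen = gv("post"),
        vaf_td_gen = gv("TD"))
      metric_rows[[length(metric_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(id = a$id, n_syn = a$n_syn, treatment = a$treatment,
                       approach = app),
        row,
        tibble::tibble(d_w = a$d_w, d_h = a$d_h))
      pm_post <- recs[[app]]$post$vaf_per_muscle
      muscle_rows[[length(muscle_rows) + 1L]] <- tibble::tibble(
        id = a$id, approach = app, target = "post",
        muscle = names(pm_post) %||% paste0("m", seq_along(pm_post)),
        vaf = unname(pm_post))
    }
  }
  structure(
    list(metrics = dplyr::bind_rows(metric_rows),
         per_muscle = dplyr::bind_rows(muscle_rows),
         fits = analysed, generic = generic,
         generic_vafs = generic_vafs,
         skipped = dplyr::bind_rows(skipped),
         config = config),
    class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf("<synergy_report> %d legs analysed, %d skipped\n",
              length(x$fits), nrow(x$skipped)))
  s <- dplyr::summarise(
    dplyr::group_by(x$metrics, .data$approach),
    vaf_pre = mean(.data$vaf_pre), vaf_post = mean(.data$vaf_post),
    vaf_td = mean(.data$vaf_td), good = mean(.data$good),
    spec = mean(.data$spec), .groups = "drop")
  print(s)
  invisible(x)
}
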