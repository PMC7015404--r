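#' Group legs by their selected number of synergies
#'
#' Partitions analysed legs into groups sharing the same selected synergy
#' count and concatenates each group's (already unit-SD scaled, per-subject)
#' pre-treatment envelope matrices along time, giving `Nm` rows and
#' `Nc * Nt * Np` columns per group.
#'
#' @param legs A list of entries, each a list with elements `id`, `emg`
#'   (a scaled [gait_cycle_matrix()]) and `n_syn` (selected synergy count);
#'   or a tibble with those columns (`emg` a list-column).
#'
#' @return A named list of `cohort_group` objects (one per distinct `n_syn`,
#'   ascending), each holding `n_syn`, `member_ids`, `n_members` and
#'   `concatenated_emg`.
#' @export
group_by_nsyn <- function(legs) {
  if (is.data.frame(legs)) {
    legs <- purrr::pmap(legs[c("id", "emg", "n_syn")], list)
  }
  if (!length(legs)) {
    abort("`legs` is empty.", class = "synkit_data_error")
  }
  nm <- vapply(legs, function(l) nrow(l$emg$data), 1L)
  if (length(unique(nm)) != 1L) {
    abort("All legs must share the same muscle count.",
          class = "synkit_data_error")
  }
  labels <- vapply(legs, function(l) as.integer(l$n_syn), 1L)
  groups <- lapply(sort(unique(labels)), function(k) {
    members <- legs[labels == k]
    data <- do.call(cbind, lapply(members, function(l) l$emg$data))
    nt <- members[[1]]$emg$n_samples
    structure(
      list(n_syn = k,
           member_ids = vapply(members, function(l) as.character(l$id), ""),
           n_members = length(members),
           concatenated_emg = gait_cycle_matrix(
             data, n_cycles = ncol(data) %/% nt, n_samples = nt,
             channel_names = members[[1]]$emg$channel_names)),
      class = "cohort_group")
  })
  setNames(groups, paste0("nsyn_", sort(unique(labels))))
}

#' @export
print.cohort_group <- function(x, ...) {
  cat(sprintf("<cohort_group> n_syn = %d, %d member(s): %s\n",
              x$n_syn, x$n_members, paste(x$member_ids, collapse = ", ")))
  invisible(x)
}

#' Extract generic synergies for a cohort group
#'
#' Runs NNMF on the group's concatenated pre-treatment matrix with the
#' group's synergy count; the activation profile is averaged over all
#' `Nc * Np` cycle windows.
#'
#' @param group A `cohort_group` from [group_by_nsyn()].
#' @param seed Integer seed.
#' @param ... Passed to [extract_synergies()] (restarts, tolerance, ...).
#'
#' @return A [synergy_set()] with `source = "generic"`.
#' @export
extract_generic <- function(group, seed = 1L, ...) {
  extract_synergies(group$concatenated_emg, group$n_syn, seed = seed,
                    source = "generic", ...)
}

#' Reconstruct member and TD data with a group's generic synergies
#'
#' Runs both reconstruction approaches (fixed generic weights, AOA; fixed
#' generic averaged profiles, WOA) against each member's pre- and
#' post-treatment matrices and each TD matrix, yielding the generic-synergy
#' VAF values (`VAF_PRE^gen`, `VAF_POST^gen`, `VAF_TD^gen`).
#'
#' @param group A `cohort_group`.
#' @param generic A generic [synergy_set()] from [extract_generic()].
#' @param pre,post Named lists of scaled [gait_cycle_matrix()] targets keyed
#'   by member id (`post` optional).
#' @param td Optional list of TD [gait_cycle_matrix()] targets; VAFs are
#'   averaged over them per member-independent approach.
#'
#' @return A tibble with columns `id`, `group`, `approach`, `source`,
#'   `target`, `vaf`.
#' @export
reconstruct_with_generic <- function(group, generic, pre, post = NULL,
                                     td = NULL) {
  rows <- list()
  add <- function(id, approach, target, v) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = id, group = group$n_syn, approach = approach,
      source = "generic", target = target, vaf = v)
  }
  td_vaf <- function(fun, fixed) {
    if (is.null(td) || !length(td)) return(NA_real_)
    mean(vapply(td, function(x) fun(fixed, x, "TD")$vaf_global, numeric(1)))
  }
  td_aoa <- td_vaf(reconstruct_aoa, generic$W)
  td_woa <- td_vaf(reconstruct_woa, generic$H_avg)
  for (id in group$member_ids) {
    add(id, "aoa", "pre",
        reconstruct_aoa(generic$W, pre[[id]], "pre")$vaf_global)
    add(id, "woa", "pre",
        reconstruct_woa(generic$H_avg, pre[[id]], "pre")$vaf_global)
    if (!is.null(post) && !is.null(post[[id]])) {
      add(id, "aoa", "post",
          reconstruct_aoa(generic$W, post[[id]], "post")$vaf_global)
      add(id, "woa", "post",
          reconstruct_woa(generic$H_avg, post[[id]], "post")$vaf_global)
    }
    add(id, "aoa", "TD", td_aoa)
    add(id, "woa", "TD", td_woa)
  }
  dplyr::bind_rows(rows)
}
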