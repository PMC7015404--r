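#' @importFrom stats cor sd quantile runif rnorm approx setNames
#' @importFrom rlang abort warn %||% .data
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "synkit_config_error")
  }
  as.integer(x)
}

check_nonneg_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name),
          class = "synkit_data_error")
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name),
          class = "synkit_data_error")
  }
  if (any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name),
          class = "synkit_data_error")
  }
  invisible(x)
}

default_muscles <- function(n = 8L) {
  nm <- c("rectus_femoris", "vastus_lateralis", "biceps_femoris_long",
          "medial_hamstrings", "tibialis_anterior", "gastrocnemius",
          "soleus", "gluteus_medius")
  if (n <= length(nm)) nm[seq_len(n)] else c(nm, paste0("muscle_", seq_len(n - length(nm)) + length(nm)))
}
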