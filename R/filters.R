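# Butterworth design in second-order sections (biquad cascade). A 6th-order
# low-pass at 6 Hz / 2000 Hz is numerically fragile in single transfer-function
# (b, a) form; the cascade form is well-conditioned at any cutoff.

butter_sos <- function(order, wn, type = c("low", "high")) {
  type <- match.arg(type)
  if (wn <= 0 || wn >= 1) {
    abort("Normalised cutoff must lie in (0, 1).", class = "synkit_config_error")
  }
  # analog prototype poles on the unit circle, left half-plane
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order) + pi / 2
  p <- exp(1i * theta)
  fs2 <- 4                      # bilinear transform with fs = 2
  warped <- fs2 * tan(pi * wn / 2)
  if (type == "low") {
    p <- warped * p             # zeros at infinity -> z = -1
    gain <- warped^order / prod(fs2 - p)
    zero_sign <- 1
  } else {
    p <- warped / p             # zeros at s = 0 -> z = +1
    gain <- fs2^order / prod(fs2 - p)
    zero_sign <- -1
  }
  pd <- (fs2 + p) / (fs2 - p)
  gain <- Re(gain)
  # pair poles into biquads: conjugate pairs, then any leftover real poles
  cplx <- pd[Im(pd) > 1e-10]
  real_p <- Re(pd[abs(Im(pd)) <= 1e-10])
  sections <- lapply(cplx, function(q) {
    list(b = c(1, 2 * zero_sign, 1), a = c(1, -2 * Re(q), Mod(q)^2))
  })
  while (length(real_p) >= 2) {
    q <- real_p[1:2]; real_p <- real_p[-(1:2)]
    sections[[length(sections) + 1L]] <-
      list(b = c(1, 2 * zero_sign, 1), a = c(1, -sum(q), prod(q)))
  }
  if (length(real_p) == 1) {
    sections[[length(sections) + 1L]] <-
      list(b = c(1, zero_sign), a = c(1, -real_p))
  }
  g <- abs(gain)^(1 / length(sections))  # spread gain across sections
  sections <- lapply(sections, function(s) { s$b <- s$b * g; s })
  sections[[1]]$b <- sections[[1]]$b * sign(gain)
  structure(list(sections = sections, order = order, wn = wn, type = type),
            class = "butter_sos")
}

sos_filter_once <- function(sos, x) {
  for (s in sos$sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  x
}

# Zero-phase application with odd reflective padding at both ends (the
# plain reverse-filter scheme rings at the edges for low cutoffs).
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  np <- min(n - 1L, 2000L)
  head_pad <- 2 * x[1] - x[(np + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- c(head_pad, x, tail_pad)
  y <- sos_filter_once(sos, y)
  y <- rev(sos_filter_once(sos, rev(y)))
  y[(np + 1L):(np + n)]
}
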