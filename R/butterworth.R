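## Butterworth band-pass design and zero-phase filtering in second-order
## sections (biquad cascade). The transfer-function (b, a) realization of a
## narrow low-frequency band-pass of this order is numerically unstable at
## double precision (pole clustering near z = 1), so design and filtering
## are done entirely in zpk/SOS form: analog low-pass prototype ->
## low-pass-to-band-pass transform -> bilinear transform -> biquad pairing.

#' Design a digital Butterworth band-pass as second-order sections
#'
#' @param order Prototype (low-pass) order; the band-pass has `2 * order`
#'   poles.
#' @param f_low,f_high Band edges as fractions of the Nyquist frequency
#'   (1.0 = Nyquist).
#' @return A numeric matrix with `order` rows and columns
#'   `b0 b1 b2 a0 a1 a2` (one biquad per row, `a0 = 1`).
#' @export
butter_bandpass_sos <- function(order, f_low, f_high) {
  stopifnot(order >= 1, f_low > 0, f_low < f_high, f_high < 1)
  fs <- 2
  ## analog prototype: poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  ## pre-warp band edges and transform low-pass -> band-pass
  w1 <- 2 * fs * tan(pi * f_low / fs)
  w2 <- 2 * fs * tan(pi * f_high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  ps <- p * bw / 2
  p_bp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  gain <- bw^order                       # `order` zeros at s = 0
  ## bilinear transform (zeros at s = 0 -> z = 1; at infinity -> z = -1)
  fs2 <- 2 * fs
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  gain_z <- gain * Re(fs2^order / prod(fs2 - p_bp))
  ## pair conjugate poles into biquads, each with zeros at z = +1 and -1;
  ## sections with poles closest to the unit circle go last
  pp <- p_z[Im(p_z) > 0]
  pp <- pp[order(Mod(pp))]
  sos <- matrix(0, nrow = order, ncol = 6)
  for (s in seq_len(order)) {
    ps1 <- pp[s]
    sos[s, ] <- c(1, 0, -1, 1, -2 * Re(ps1), Mod(ps1)^2)
  }
  sos[1, 1:3] <- sos[1, 1:3] * gain_z
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

## Steady-state (unit-step) initial conditions of one biquad, as used to
## suppress start-up transients in forward-backward filtering.
biquad_zi <- function(b, a) {
  A <- rbind(c(1 + a[2], -1), c(a[3], 1))
  B <- c(b[2] - a[2] * b[1], b[3] - a[3] * b[1])
  solve(A, B)
}

sos_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    zi[s, ] <- scale * biquad_zi(b, a)
    scale <- scale * sum(b) / sum(a)
  }
  zi
}

#' Apply a second-order-section filter, zero-phase or causal
#'
#' Zero-phase mode filters forward and backward with odd-reflection padding
#' and steady-state initial conditions, so the output has no group delay
#' and strongly reduced edge transients.
#'
#' @param sos SOS matrix from [butter_bandpass_sos()].
#' @param x Numeric series.
#' @param zero_phase Forward-backward if `TRUE` (default), single causal
#'   pass otherwise.
#' @param padlen Reflection pad length; default `3 * (2 * nrow(sos) + 1)`,
#'   capped at `length(x) - 1`.
#' @return Filtered series, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x, zero_phase = TRUE, padlen = NULL) {
  n <- length(x)
  zi <- sos_zi(sos)
  if (!zero_phase) {
    return(.sosfilt(sos, x, zi * x[1]))
  }
  if (is.null(padlen)) padlen <- 3 * (2 * nrow(sos) + 1)
  padlen <- min(padlen, n - 1)
  if (padlen < 1) stop("series too short to filter")
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .sosfilt(sos, ext, zi * ext[1])
  y <- rev(.sosfilt(sos, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Frequency response magnitude of an SOS filter
#'
#' @param sos SOS matrix.
#' @param f Frequencies as fractions of Nyquist.
#' @return `|H|` at each frequency (single-pass response; a zero-phase
#'   application has magnitude `|H|^2`).
#' @export
sos_freq_response <- function(sos, f) {
  z <- exp(-1i * pi * f)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  unname(Mod(h))
}
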