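#' Call duration from the amplitude envelope
#'
#' Duration is the time between the first and last point at which the
#' short-time RMS envelope exceeds `threshold_db` relative to its maximum.
#' This automates the on-screen cursor measurement used in desktop sound
#' analysis; the threshold is configurable.
#'
#' @param w a `waveform`.
#' @param threshold_db threshold below the envelope maximum, in dB
#'   (default -20).
#' @param smooth_s RMS smoothing window in seconds (default 1.5 ms).
#' @return duration in seconds.
#' @export
measure_duration <- function(w, threshold_db = -20, smooth_s = 0.0015) {
  x <- w$samples
  if (length(x) == 0 || all(x == 0)) stop_volecall("silent waveform")
  win <- max(3L, round(smooth_s * w$sampling_rate_hz))
  env2 <- as.numeric(stats::filter(x^2, rep(1 / win, win), sides = 2))
  env2[is.na(env2)] <- 0
  thr <- max(env2) * 10^(threshold_db / 10)
  idx <- which(env2 >= thr)
  (idx[length(idx)] - idx[1] + 1) / w$sampling_rate_hz
}

#' Peak frequency of a power spectrum
#'
#' Frequency of the bin with maximum power; ties are broken toward the lowest
#' frequency.
#'
#' @param ps a `power_spectrum`.
#' @return frequency in Hz.
#' @export
peak_frequency <- function(ps) {
  if (sum(ps$power) <= 0) stop_volecall("zero power spectrum")
  ps$bin_freqs_hz[which.max(ps$power)]  # which.max takes the first maximum
}

#' Energy quartiles of a power spectrum
#'
#' The lower, medium and upper quartiles are the frequencies below which 25,
#' 50 and 75% of the total spectral energy lies: for each fraction, the lowest
#' bin frequency at which the cumulative power reaches that fraction of the
#' total.
#'
#' @param ps a `power_spectrum`.
#' @param probs energy fractions (default 0.25, 0.5, 0.75).
#' @return named numeric vector `q25_hz`, `q50_hz`, `q75_hz` (for the default
#'   `probs`).
#' @export
energy_quartiles <- function(ps, probs = c(0.25, 0.5, 0.75)) {
  total <- sum(ps$power)
  if (total <= 0) stop_volecall("zero power spectrum")
  cum <- cumsum(ps$power)
  out <- vapply(probs, function(p)
    ps$bin_freqs_hz[which(cum >= p * total - 1e-12 * total)[1]], numeric(1))
  names(out) <- paste0("q", round(100 * probs), "_hz")
  out
}

#' Spectral entropy (flatness) of a power spectrum
#'
#' The ratio of the geometric to the arithmetic mean of the per-bin power: 1
#' for a flat (white) spectrum, approaching 0 for a pure tone. Zero-power bins
#' are floored at `1e-12 * max(power)` before the geometric mean, which is
#' otherwise undefined.
#'
#' @param ps a `power_spectrum`.
#' @return entropy in \[0, 1\].
#' @export
spectral_entropy <- function(ps) {
  p <- ps$power
  if (sum(p) <= 0) stop_volecall("zero power spectrum")
  p <- pmax(p, 1e-12 * max(p))
  gm <- exp(mean(log(p)))
  min(gm / mean(p), 1)
}
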