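#' Short-time Fourier magnitude spectrogram
#'
#' Computes the magnitude STFT of a mono waveform with the framing used
#' throughout the package: Hamming window, `fft_size` points and fractional
#' `overlap`, giving a frame step of `fft_size * (1 - overlap)` samples and
#' `floor((N - fft_size) / step) + 1` frames. Inputs shorter than one window
#' are zero-padded to a single frame. At the default 22050 Hz sampling rate,
#' 512-point FFT and 87.5% overlap this yields 43 Hz frequency resolution and
#' a 2.9 ms frame step.
#'
#' @param w a `waveform`.
#' @param fft_size FFT length in samples (default 512).
#' @param overlap fractional window overlap in \[0, 1) (default 0.875).
#' @param window window type; only `"hamming"` is provided.
#' @return object of class `spectrogram`: list with `magnitude`
#'   (frames x bins matrix, bins = fft_size/2 + 1), `frame_times_s`,
#'   `bin_freqs_hz`, `window`, `fft_size`, `overlap_fraction`,
#'   `sampling_rate_hz`.
#' @examples
#' w <- synthesize(list(duration_s = 0.05, f0max_hz = 2000,
#'                      modulation_range_hz = 0, n_harmonics = 3,
#'                      structure = "harmonic", noise_fraction = 0), seed = 1)
#' sg <- compute_spectrogram(w)
#' dim(sg$magnitude)
#' @export
compute_spectrogram <- function(w, fft_size = 512, overlap = 0.875,
                                window = "hamming") {
  x <- w$samples
  if (length(x) == 0) stop_volecall("empty waveform")
  if (overlap < 0 || overlap >= 1) stop_volecall("overlap must be in [0, 1)")
  if (!identical(window, "hamming"))
    stop_volecall("only the hamming window is supported")
  rate <- w$sampling_rate_hz
  step <- round(fft_size * (1 - overlap))
  if (step < 1) stop_volecall("overlap too large for this fft_size")
  if (length(x) < fft_size) x <- c(x, numeric(fft_size - length(x)))
  n_frames <- floor((length(x) - fft_size) / step) + 1L
  starts <- (seq_len(n_frames) - 1L) * step
  win <- signal::hamming(fft_size)
  frames <- vapply(starts, function(s) x[s + seq_len(fft_size)] * win,
                   numeric(fft_size))
  spec <- stats::mvfft(frames)  # columns = frames
  n_bins <- fft_size / 2 + 1L
  mag <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))
  structure(list(magnitude = mag,
                 frame_times_s = (starts + fft_size / 2) / rate,
                 bin_freqs_hz = (seq_len(n_bins) - 1) * rate / fft_size,
                 window = "hamming", fft_size = as.integer(fft_size),
                 overlap_fraction = overlap, sampling_rate_hz = rate),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "spectrogram: %d frames x %d bins (%s, FFT %d, overlap %.1f%%, %.1f Hz/bin)\n",
    nrow(x$magnitude), ncol(x$magnitude), x$window, x$fft_size,
    100 * x$overlap_fraction, x$bin_freqs_hz[2]))
  invisible(x)
}

#' Per-call average power spectrum
#'
#' Collapses a spectrogram to one power spectrum per call by averaging the
#' per-bin power over the non-silent frames (frames whose total energy is at
#' least `silence_threshold` of the loudest frame's). This single spectrum is
#' what the scalar call parameters (peak frequency, energy quartiles, spectral
#' entropy) are read from.
#'
#' @param s a `spectrogram`.
#' @param silence_threshold fraction of the maximum frame energy below which a
#'   frame is treated as silence (default 0.01).
#' @return object of class `power_spectrum`: list with `power` and
#'   `bin_freqs_hz`.
#' @export
call_power_spectrum <- function(s, silence_threshold = 0.01) {
  pow <- s$magnitude^2
  frame_energy <- rowSums(pow)
  if (max(frame_energy) <= 0)
    stop_volecall("all-silent spectrogram: no power spectrum")
  keep <- frame_energy >= silence_threshold * max(frame_energy)
  structure(list(power = colMeans(pow[keep, , drop = FALSE]),
                 bin_freqs_hz = s$bin_freqs_hz),
            class = "power_spectrum")
}
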