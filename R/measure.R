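#' Measure the standard call parameters of one waveform
#'
#' Composes the full measurement chain for a single call: duration from the
#' amplitude envelope, the per-call average power spectrum, peak frequency,
#' the 25/50/75% energy quartiles, spectral entropy, structural typing
#' (harmonic / noise / mixed), and — for calls with a discernible harmonic
#' relation — the maximum fundamental frequency and its modulation range. The
#' fundamental of noise calls is not measured and is reported as `NA`.
#'
#' @param w a `waveform`.
#' @param fft_size,overlap spectrogram settings (defaults 512 and 0.875).
#' @param threshold_db duration threshold, dB below the envelope maximum.
#' @param f0_search_hz fundamental search range in Hz.
#' @param harmonic_threshold,noise_threshold structural typing thresholds,
#'   see [classify_structure()].
#' @return one-row data.frame with columns `duration_s`, `peak_hz`, `q25_hz`,
#'   `q50_hz`, `q75_hz`, `entropy`, `f0max_hz`, `modulation_range_hz`,
#'   `structure`.
#' @examples
#' spec <- sample_call_specs(default_profiles()$bank, 1, seed = 3)
#' measure(synthesize(spec, seed = 3))
#' @export
measure <- function(w, fft_size = 512, overlap = 0.875, threshold_db = -20,
                    f0_search_hz = c(800, 6000), harmonic_threshold = 0.8,
                    noise_threshold = 0.2) {
  if (length(w$samples) == 0 || all(w$samples == 0))
    stop_volecall("silent waveform")
  sg <- compute_spectrogram(w, fft_size = fft_size, overlap = overlap)
  ps <- call_power_spectrum(sg)
  q <- energy_quartiles(ps)
  structure_cls <- classify_structure(sg, harmonic_threshold, noise_threshold,
                                      f0_search_hz)
  f0max <- NA_real_
  mod <- NA_real_
  if (structure_cls != "noise") {
    tr <- track_fundamental(sg, f0_search_hz)
    f0max <- tr$f0max_hz
    mod <- tr$modulation_range_hz
  }
  data.frame(duration_s = measure_duration(w, threshold_db),
             peak_hz = peak_frequency(ps),
             q25_hz = q[["q25_hz"]], q50_hz = q[["q50_hz"]],
             q75_hz = q[["q75_hz"]],
             entropy = spectral_entropy(ps),
             f0max_hz = f0max, modulation_range_hz = mod,
             structure = structure_cls,
             stringsAsFactors = FALSE)
}

#' Synthesize and measure a batch of calls
#'
#' Convenience wrapper running [synthesize()] and [measure()] over a
#' specification table, with one derived seed per call so the batch is
#' reproducible.
#'
#' @param specs data.frame of call specifications ([sample_call_specs()]).
#' @param sampling_rate_hz sampling rate for synthesis.
#' @param seed base integer seed; call i uses `seed + i`.
#' @param ... further arguments passed to [measure()].
#' @return data.frame: `specs`' `group` column (if present) plus the
#'   measurement columns, one row per call.
#' @export
measure_calls <- function(specs, sampling_rate_hz = 22050, seed = 1, ...) {
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    w <- synthesize(specs[i, ], sampling_rate_hz, seed = seed + i)
    measure(w, ...)
  })
  out <- do.call(rbind, rows)
  if ("group" %in% names(specs)) out <- cbind(group = specs$group, out)
  rownames(out) <- NULL
  out
}
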