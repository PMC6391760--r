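# Fundamental-frequency tracking and structural call typing, both built on
# the per-frame harmonic-comb fit implemented in .frame_f0_score below.

# Interpolated log-power of one frame at arbitrary frequencies: quadratic
# (parabolic) interpolation of log power through the three bins around the
# target, a standard refinement below bin resolution.
.interp_log_power <- function(log_pow, bin_step, freqs) {
  n <- length(log_pow)
  pos <- freqs / bin_step + 1
  j <- pmin(pmax(round(pos), 2L), n - 1L)
  d <- pos - j
  y0 <- log_pow[j - 1L]; y1 <- log_pow[j]; y2 <- log_pow[j + 1L]
  y1 + d * (y2 - y0) / 2 + d^2 * (y2 - 2 * y1 + y0) / 2
}

# Comb score over a fixed number of terms so candidates are comparable: log
# power relative to the frame maximum, capped at -`cap` nats. A partial that
# should be in band but is absent costs the full cap; one above Nyquist costs
# slightly less (`oob`) — it cannot exist, so its absence is weaker evidence
# against the candidate. This resolves the octave ambiguities a raw
# sum-over-available-partials score suffers from.
.frame_f0_score <- function(log_pow, bin_step, candidates, nyquist,
                            n_harmonics = 5L, cap = 10, oob = 8) {
  lp_rel <- log_pow - max(log_pow)
  vapply(candidates, function(f0) {
    fk <- seq_len(n_harmonics) * f0
    inb <- fk < nyquist - bin_step
    v <- rep(-oob, n_harmonics)
    if (any(inb))
      v[inb] <- pmax(.interp_log_power(lp_rel, bin_step, fk[inb]), -cap)
    # minute bonus toward higher candidates breaks the exact tie between a
    # fundamental and its sub-octave when upper partials are missing
    sum(v) + 0.3 * f0 / nyquist
  }, numeric(1))
}

#' Track the fundamental frequency of a harmonic call
#'
#' For every voiced frame (frame energy at least `silence_threshold` of the
#' loudest frame), the fundamental is estimated as the candidate frequency
#' maximizing the harmonic comb score: the sum of parabolic-interpolated log
#' power at the first `n_harmonics` multiples of the candidate below Nyquist.
#' Candidates cover `f0_search_hz` on a quarter-bin grid, with a final
#' parabolic refinement of the score peak. The maximum fundamental over the
#' track and the modulation range (max - min) summarize the arch-shaped
#' frequency modulation of these calls.
#'
#' @param s a `spectrogram`.
#' @param f0_search_hz search range in Hz (default 800-6000, bracketing the
#'   1.5-3.8 kHz species means with margin against octave errors).
#' @param n_harmonics comb length K (default 5).
#' @param silence_threshold voiced-frame energy threshold as a fraction of the
#'   maximum frame energy (default 0.01).
#' @param min_harmonicity minimum harmonicity (see [classify_structure()]) a
#'   frameset must reach to count as voiced at all; below it the call is
#'   treated as a noise call (default 0.1).
#' @return list with `f0max_hz`, `modulation_range_hz`, `f0_track_hz`
#'   (per-voiced-frame estimates) and `frame_times_s`.
#' @export
track_fundamental <- function(s, f0_search_hz = c(800, 6000),
                              n_harmonics = 5L, silence_threshold = 0.01,
                              min_harmonicity = 0.1) {
  pow <- s$magnitude^2
  frame_energy <- rowSums(pow)
  if (max(frame_energy) <= 0) stop_volecall("silent spectrogram")
  voiced <- which(frame_energy >= silence_threshold * max(frame_energy))
  if (harmonicity_index(s, f0_search_hz, silence_threshold) <
      min_harmonicity)
    stop_volecall("noise call: no harmonic relation between components, ",
                  "f0 undefined")
  bin_step <- s$bin_freqs_hz[2]
  nyq <- s$bin_freqs_hz[length(s$bin_freqs_hz)]
  cand <- seq(f0_search_hz[1], f0_search_hz[2], by = bin_step / 4)
  floor_pow <- 1e-12 * max(pow)
  track <- vapply(voiced, function(i) {
    lp <- log(pmax(pow[i, ], floor_pow))
    sc <- .frame_f0_score(lp, bin_step, cand, nyq, n_harmonics)
    j <- which.max(sc)
    f0 <- cand[j]
    if (j > 1L && j < length(cand) && all(is.finite(sc[j + c(-1L, 1L)]))) {
      denom <- sc[j - 1L] - 2 * sc[j] + sc[j + 1L]
      if (denom < 0)
        f0 <- f0 + 0.5 * (sc[j - 1L] - sc[j + 1L]) / denom * (bin_step / 4)
    }
    f0
  }, numeric(1))
  # continuity: a running median removes isolated octave slips on frames
  # where modulation smears the upper partials
  if (length(track) >= 5L)
    track <- stats::runmed(track, 5L, endrule = "median")
  list(f0max_hz = max(track),
       modulation_range_hz = max(track) - min(track),
       f0_track_hz = track,
       frame_times_s = s$frame_times_s[voiced])
}

#' Harmonicity index of a call
#'
#' Fraction of the call's spectral energy explained by the best-fitting
#' harmonic comb, rescaled against the fraction a flat spectrum would place on
#' the comb bins by chance: `(comb_energy/total - expected) / (1 - expected)`,
#' clipped to \[0, 1\]. The comb covers +/-2 bins (one Hamming main lobe)
#' around every multiple of the fitted fundamental. A pure harmonic stack
#' scores near 1, broadband noise near 0.
#'
#' @inheritParams track_fundamental
#' @return harmonicity in \[0, 1\].
#' @export
harmonicity_index <- function(s, f0_search_hz = c(800, 6000),
                              silence_threshold = 0.01) {
  pow <- s$magnitude^2
  frame_energy <- rowSums(pow)
  if (max(frame_energy) <= 0) stop_volecall("silent spectrogram")
  keep <- which(frame_energy >= silence_threshold * max(frame_energy))
  n_bins <- ncol(pow)
  bin_step <- s$bin_freqs_hz[2]
  nyq <- s$bin_freqs_hz[n_bins]
  floor_pow <- 1e-12 * max(pow)
  cand <- seq(f0_search_hz[1], f0_search_hz[2], by = bin_step / 2)
  # per-frame comb fit: the fundamental is locally stationary within a frame,
  # while the call-average spectrum is smeared by the frequency modulation
  fracs <- vapply(keep, function(i) {
    p <- pow[i, ]
    lp <- log(pmax(p, floor_pow))
    sc <- .frame_f0_score(lp, bin_step, cand, nyq, n_harmonics = 5L)
    f0 <- cand[which.max(sc)]
    k <- seq_len(floor(nyq / f0))
    comb_bins <- unique(unlist(lapply(k, function(kk)
      round(kk * f0 / bin_step) + 1L + (-2L:2L))))
    comb_bins <- comb_bins[comb_bins >= 1L & comb_bins <= n_bins]
    frac <- sum(p[comb_bins]) / sum(p)
    expected <- length(comb_bins) / n_bins
    max(0, min(1, (frac - expected) / (1 - expected)))
  }, numeric(1))
  stats::weighted.mean(fracs, frame_energy[keep])
}

#' Structural call typing: harmonic, noise or mixed
#'
#' Calls are typed by harmonicity: at least `harmonic_threshold` of the
#' comb-explained energy fraction gives a harmonic call, at most
#' `noise_threshold` a noise call (no discernible harmonic relation between
#' the component frequencies), anything between is mixed (a harmonic stack
#' with broadband noise over it).
#'
#' @inheritParams track_fundamental
#' @param harmonic_threshold harmonicity at or above which a call is
#'   `"harmonic"` (default 0.8).
#' @param noise_threshold harmonicity at or below which a call is `"noise"`
#'   (default 0.2).
#' @return one of `"harmonic"`, `"noise"`, `"mixed"`.
#' @export
classify_structure <- function(s, harmonic_threshold = 0.8,
                               noise_threshold = 0.2,
                               f0_search_hz = c(800, 6000)) {
  h <- harmonicity_index(s, f0_search_hz)
  if (h >= harmonic_threshold) "harmonic"
  else if (h <= noise_threshold) "noise"
  else "mixed"
}
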