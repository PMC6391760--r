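# Shared fixture builders: everything is generated in code at test time.

make_wave <- function(x, rate = 22050) {
  structure(list(samples = x, sampling_rate_hz = rate), class = "waveform")
}

tone_wave <- function(freq, dur = 0.1, rate = 22050, amp = 0.9) {
  n <- round(dur * rate)
  make_wave(amp * sin(2 * pi * freq * (seq_len(n) - 1) / rate), rate)
}

make_ps <- function(power, freqs = seq(0, by = 43.066, length.out =
                                         length(power))) {
  structure(list(power = power, bin_freqs_hz = freqs),
            class = "power_spectrum")
}

# A stationary (or arch-modulated) harmonic-stack call spec with short ramps.
stack_spec <- function(f0, dur = 0.1, mod = 0, nh = 5, nf = 0, q50 = NULL) {
  list(duration_s = dur, f0max_hz = f0, modulation_range_hz = mod,
       n_harmonics = nh, noise_fraction = nf, q50_hz = q50,
       attack = 0.02, decay = 0.02, noise_band_hz = c(1000, 10000))
}

# Two Gaussian clouds with a mean shift on the first feature.
two_group_data <- function(n1 = 40, n2 = 40, p = 3, shift = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1),
             matrix(rnorm(n2 * p), n2))
  x[seq_len(n1), 1] <- x[seq_len(n1), 1] + shift
  d <- as.data.frame(x)
  names(d) <- paste0("f", seq_len(p))
  d$group <- rep(c("a", "b"), c(n1, n2))
  d
}

# Ground-truth parent draws over the analysis feature set (no audio).
parent_feature_draws <- function(seed) {
  pr <- default_profiles()
  feats <- c("duration_s", "q50_hz", "entropy")
  d <- rbind(sample_call_specs(pr$tien_shan, 118, seed = seed),
             sample_call_specs(pr$bank, 78, seed = seed + 500))
  d[c("group", feats)]
}
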