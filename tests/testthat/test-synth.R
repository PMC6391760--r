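test_that("waveform length honours the duration contract", {
  w <- synthesize(stack_spec(3000, dur = 0.027), sampling_rate_hz = 22050,
                  seed = 1)
  expect_length(w$samples, 595)  # round(0.027 * 22050)
  expect_equal(max(abs(w$samples)), 0.9)
  w2 <- synthesize(stack_spec(2000, dur = 0.1), sampling_rate_hz = 44100,
                   seed = 1)
  expect_length(w2$samples, 4410)
})

test_that("identical spec and seed give bit-identical waveforms", {
  spec <- sample_call_specs(default_profiles()$bank, 1, seed = 4)
  w1 <- synthesize(spec, seed = 99)
  w2 <- synthesize(spec, seed = 99)
  expect_identical(w1$samples, w2$samples)
  w3 <- synthesize(spec, seed = 100)
  expect_false(identical(w1$samples, w3$samples))
})

test_that("invalid specs are rejected", {
  expect_error(synthesize(stack_spec(1000, mod = 1500)), "exceed")
  expect_error(synthesize(list(duration_s = -1, f0max_hz = 1000)), "positive")
  bad <- stack_spec(1000); bad$noise_fraction <- 1.4
  expect_error(synthesize(bad), "noise_fraction")
})

test_that("a noiseless stack shows spectral peaks at harmonics of f0", {
  f0 <- 1100; nh <- 5
  w <- synthesize(stack_spec(f0, dur = 0.2, nh = nh), seed = 2,
                  bg_noise_amp = 0)
  # independent oracle: direct DFT of the whole generated signal
  p <- Mod(fft(w$samples))^2
  n <- length(w$samples)
  p <- p[seq_len(n %/% 2)]
  med <- median(p)
  hits <- vapply(seq_len(nh), function(k) {
    bin <- round(k * f0 * n / w$sampling_rate_hz) + 1
    win <- p[max(1, bin - 3):min(length(p), bin + 3)]
    max(win) > 100 * med
  }, logical(1))
  expect_gte(sum(hits), nh - 1)
})

test_that("pure-noise specs produce no detectable harmonic relation", {
  w <- synthesize(stack_spec(3000, dur = 0.06, nf = 1), seed = 5)
  sg <- compute_spectrogram(w)
  expect_identical(classify_structure(sg), "noise")
  expect_error(track_fundamental(sg), "noise call")
})

test_that("measured entropy increases with the noise fraction", {
  nfs <- seq(0.02, 0.95, length.out = 50)
  ent <- vapply(seq_along(nfs), function(i) {
    w <- synthesize(stack_spec(2800, dur = 0.05, nh = 5, nf = nfs[i],
                               q50 = 4000), seed = 300 + i)
    spectral_entropy(call_power_spectrum(compute_spectrogram(w)))
  }, numeric(1))
  expect_gt(cor(nfs, ent, method = "spearman"), 0)
})

test_that("noiseless calls round-trip through the measurement chain", {
  for (f0 in seq(1000, 5000, by = 1000)) {
    dur <- 0.1
    w <- synthesize(stack_spec(f0, dur = dur, nh = 4), seed = f0,
                    bg_noise_amp = 0)
    m <- measure(w)
    expect_lt(abs(m$duration_s - dur), 0.002)
    expect_lt(abs(m$f0max_hz - f0), 43.1,
              label = sprintf("f0 recovery at %d Hz", f0))
  }
})

test_that("WAV files round-trip in both encodings", {
  w <- synthesize(stack_spec(2500, dur = 0.05, nf = 0.3), seed = 8)
  p16 <- tempfile(fileext = ".wav")
  p32 <- tempfile(fileext = ".wav")
  on.exit(unlink(c(p16, p32)))
  write_wav(w, p16, bits = 16)
  write_wav(w, p32, bits = 32)
  r16 <- read_wav(p16)
  r32 <- read_wav(p32)
  expect_equal(r16$sampling_rate_hz, 22050)
  expect_equal(r16$samples, w$samples, tolerance = 1e-4)
  expect_equal(r32$samples, w$samples, tolerance = 1e-6)
  m0 <- measure(w); m16 <- measure(r16)
  expect_equal(m16$q50_hz, m0$q50_hz)
  expect_equal(m16$entropy, m0$entropy, tolerance = 1e-3)
})
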