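test_that("peak frequency takes the maximum bin, lowest frequency on ties", {
  ps <- make_ps(c(0, 0, 5, 1, 0), freqs = c(0, 1000, 2800, 4000, 5000))
  expect_equal(peak_frequency(ps), 2800)
  flat <- make_ps(rep(1, 5), freqs = c(0, 1000, 2000, 3000, 4000))
  expect_equal(peak_frequency(flat), 0)
  expect_error(peak_frequency(make_ps(rep(0, 5))), "zero")
})

test_that("energy quartiles match hand-checkable spectra", {
  one <- make_ps(c(0, 0, 7, 0), freqs = c(0, 500, 1500, 2500))
  expect_equal(unname(energy_quartiles(one)), c(1500, 1500, 1500))
  flat <- make_ps(rep(1, 8), freqs = 100 * (0:7))
  q <- energy_quartiles(flat)
  expect_equal(unname(q[["q50_hz"]]), 300)  # cumulative hits 4/8 at bin 4
  expect_error(energy_quartiles(make_ps(rep(0, 4))), "zero")
})

test_that("quartiles agree exactly with a brute-force cumulative scan", {
  brute <- function(power, freqs, frac) {
    total <- sum(power); acc <- 0
    for (i in seq_along(power)) {
      acc <- acc + power[i]
      if (acc >= frac * total - 1e-12 * total) return(freqs[i])
    }
  }
  set.seed(42)
  for (i in 1:200) {
    power <- runif(20)^2
    freqs <- 43 * (0:19)
    ps <- make_ps(power, freqs)
    q <- energy_quartiles(ps)
    expect_identical(unname(q),
                     c(brute(power, freqs, 0.25), brute(power, freqs, 0.5),
                       brute(power, freqs, 0.75)))
  }
})

test_that("quartiles are ordered on arbitrary random spectra", {
  set.seed(7)
  for (i in 1:100) {
    q <- energy_quartiles(make_ps(rexp(257)))
    expect_true(q[["q25_hz"]] <= q[["q50_hz"]] &&
                  q[["q50_hz"]] <= q[["q75_hz"]])
  }
})

test_that("spectral entropy matches its defining ratio", {
  expect_equal(spectral_entropy(make_ps(rep(3.7, 100))), 1)
  # oracle: geometric mean 2, arithmetic mean 2.5
  expect_equal(spectral_entropy(make_ps(c(1, 4))), 0.8)
  dominant <- make_ps(c(rep(0, 200), 1, rep(0, 56)))
  expect_lte(spectral_entropy(dominant), 0.01)
  set.seed(3)
  p <- rexp(257)
  expect_true(spectral_entropy(make_ps(p)) >= 0 &&
                spectral_entropy(make_ps(p)) <= 1)
  expect_equal(spectral_entropy(make_ps(17 * p)),
               spectral_entropy(make_ps(p)))
})

test_that("scalar spectral parameters ignore waveform amplitude", {
  w <- synthesize(stack_spec(2400, dur = 0.06, nf = 0.4, q50 = 5000),
                  seed = 21)
  w_small <- make_wave(0.05 * w$samples)
  ps1 <- call_power_spectrum(compute_spectrogram(w))
  ps2 <- call_power_spectrum(compute_spectrogram(w_small))
  expect_equal(peak_frequency(ps1), peak_frequency(ps2))
  expect_equal(energy_quartiles(ps1), energy_quartiles(ps2))
  expect_equal(spectral_entropy(ps1), spectral_entropy(ps2))
})

test_that("duration measurement tracks the envelope, not the padding", {
  rate <- 22050
  rect <- make_wave(c(numeric(200), rep(0.8, round(0.027 * rate)),
                      numeric(200)), rate)
  expect_lt(abs(measure_duration(rect) - 0.027), 0.002)
  padded <- make_wave(c(numeric(round(0.1 * rate)), rect$samples,
                        numeric(round(0.1 * rate))), rate)
  expect_lt(abs(measure_duration(padded) - measure_duration(rect)), 0.002)
  expect_error(measure_duration(make_wave(numeric(100))), "silent")
})

test_that("entropy never decreases as broadband noise is added on top", {
  base <- synthesize(stack_spec(2600, dur = 0.06, nh = 5), seed = 31,
                     bg_noise_amp = 0)
  set.seed(44)
  noise <- rnorm(length(base$samples))
  levels <- seq(0, 0.8, by = 0.1)
  ent <- vapply(levels, function(a) {
    w <- make_wave(base$samples + a * noise)
    spectral_entropy(call_power_spectrum(compute_spectrogram(w)))
  }, numeric(1))
  expect_gt(cor(levels, ent, method = "spearman"), 0.9)
  expect_true(all(diff(ent) > -0.02))
})
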