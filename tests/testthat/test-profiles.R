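test_that("default profiles carry the published group statistics", {
  pr <- default_profiles()
  expect_named(pr, c("tien_shan", "hybrid", "bank"))
  expect_equal(pr$tien_shan$means[["duration_s"]], 0.027)
  expect_equal(pr$tien_shan$se[["duration_s"]], 0.001)
  expect_equal(pr$bank$means[["entropy"]], 0.637)
  expect_equal(pr$bank$se[["entropy"]], 0.004)
  expect_equal(pr$hybrid$means[["f0max_hz"]], 3200)
  expect_equal(pr$hybrid$se[["f0max_hz"]], 100)
  expect_equal(vapply(pr, function(p) p$n_calls_reference, 1L),
               c(tien_shan = 118L, hybrid = 108L, bank = 78L))
  for (p in pr) {
    expect_equal(sum(p$structure_mix), 1, tolerance = 1e-9)
    expect_true(all(p$harmonic_count_range >= 3 &
                      p$harmonic_count_range <= 10))
    expect_true(all(p$se > 0))
    expect_gt(p$means[["entropy"]], 0)
    expect_lt(p$means[["entropy"]], 1)
  }
})

test_that("profile validation rejects malformed inputs", {
  pr <- default_profiles()$bank
  expect_error(species_profile("x", 10, pr$means, pr$se,
                               structure_mix = c(harmonic = 0.5, noise = 0.2,
                                                 mixed = 0.2)),
               "sum to 1")
  expect_error(species_profile("x", 10, pr$means, pr$se,
                               harmonic_count_range = c(2, 10)),
               "3, 10")
  bad <- pr$means; bad[["entropy"]] <- 1.2
  expect_error(species_profile("x", 10, bad, pr$se), "entropy")
})

test_that("call-spec draws are reproducible and respect validity bounds", {
  pr <- default_profiles()
  a <- sample_call_specs(pr$hybrid, 5, seed = 7)
  b <- sample_call_specs(pr$hybrid, 5, seed = 7)
  expect_identical(a, b)
  big <- do.call(rbind, lapply(pr, sample_call_specs, n = 400, seed = 3))
  expect_true(all(big$duration_s > 0.002))
  expect_true(all(big$f0max_hz > big$modulation_range_hz))
  expect_true(all(big$modulation_range_hz >= 0))
  expect_true(all(big$entropy > 0 & big$entropy < 1))
  expect_true(all(big$structure %in% c("harmonic", "noise", "mixed")))
  expect_true(all(big$noise_fraction[big$structure == "harmonic"] == 0))
  expect_true(all(big$noise_fraction[big$structure == "noise"] == 1))
  mixed_nf <- big$noise_fraction[big$structure == "mixed"]
  expect_true(all(mixed_nf > 0 & mixed_nf < 1))
  expect_true(all(big$n_harmonics >= 3 & big$n_harmonics <= 10))
})

test_that("a vanishing standard error collapses draws onto the means", {
  pr <- default_profiles()$tien_shan
  degenerate <- species_profile("d", 118, pr$means,
                                se = pr$se * 1e-12,
                                structure_mix = pr$structure_mix)
  d <- sample_call_specs(degenerate, 10, seed = 1)
  expect_equal(d$duration_s, rep(pr$means[["duration_s"]], 10),
               tolerance = 1e-6)
  expect_equal(d$f0max_hz, rep(pr$means[["f0max_hz"]], 10), tolerance = 1e-6)
})

test_that("population draws recover the truncated-normal target means", {
  pr <- default_profiles()
  bounds <- list(duration_s = c(0.002, Inf), f0max_hz = c(350, 9000),
                 q50_hz = c(100, 10800), entropy = c(0.01, 0.99))
  # closed-form truncated-normal mean, the independent oracle
  tmean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  n <- 1000
  for (name in names(pr)) {
    p <- pr[[name]]
    sds <- p$se * sqrt(p$n_calls_reference)
    d <- sample_call_specs(p, n, seed = 11)
    for (par in names(bounds)) {
      target <- tmean(p$means[[par]], sds[[par]],
                      bounds[[par]][1], bounds[[par]][2])
      expect_lt(abs(mean(d[[par]]) - target), 4 * sds[[par]] / sqrt(n),
                label = sprintf("%s %s mean error", name, par))
    }
    # modulation range: the oracle averages the conditional truncated mean
    # over the drawn f0max values (upper bound depends on f0max)
    target_mod <- mean(vapply(d$f0max_hz, function(f)
      tmean(p$means[["modulation_range_hz"]], sds[["modulation_range_hz"]],
            0, f - 200), numeric(1)))
    expect_lt(abs(mean(d$modulation_range_hz) - target_mod),
              4 * sds[["modulation_range_hz"]] / sqrt(n))
    # where truncation is negligible the raw published mean is recovered too
    for (par in c("q50_hz", "entropy")) {
      expect_lt(abs(mean(d[[par]]) - p$means[[par]]),
                4 * sds[[par]] / sqrt(n),
                label = sprintf("%s %s raw mean", name, par))
    }
  }
  d <- sample_call_specs(pr$tien_shan, n, seed = 1)
  expect_lt(abs(mean(d$duration_s) - 0.027),
            3 * 0.001 * sqrt(118) / sqrt(n))
})
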