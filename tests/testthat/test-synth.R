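# Synthetic pulse generator: morphology, determinism, closed-loop SNR
# targeting and corpus assembly.

test_that("clean pulse has its spectral peak at the configured heart rate", {
  cfg <- synth_config(duration_s = 60, hr_mean_bpm = 72, hr_sd_bpm = 0,
                      seed = 3)
  s <- generate_clean_pulse(cfg)
  x <- s$values - mean(s$values)
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) * s$fs / n
  in_band <- freqs >= 0.7 & freqs <= 3.5
  peak <- freqs[in_band][which.max(p[in_band])]
  expect_equal(peak, 1.2, tolerance = s$fs / n + 1e-9)
})

test_that("zero notch amplitude gives one local maximum per beat", {
  cfg <- synth_config(duration_s = 30, hr_mean_bpm = 75, hr_sd_bpm = 0,
                      notch_amp = 0, seed = 4)
  s <- generate_clean_pulse(cfg)
  x <- s$values
  n_peaks <- sum(diff(sign(diff(x))) < 0 &
                   x[2:(length(x) - 1)] > mean(x) + 0.2 * sd(x))
  expected_beats <- 30 * 75 / 60
  expect_lte(abs(n_peaks - expected_beats), 1)
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(seed = 99)
  a <- generate_clean_pulse(cfg)
  b <- generate_clean_pulse(cfg)
  expect_identical(a$values, b$values)
  na <- corrupt_to_snr(a, cfg)
  nb <- corrupt_to_snr(b, cfg)
  expect_identical(na$values, nb$values)
  c1 <- generate_corpus(2, default_config_sampler(
    duration_range_s = c(15, 15)), seed = 7)
  c2 <- generate_corpus(2, default_config_sampler(
    duration_range_s = c(15, 15)), seed = 7)
  expect_identical(c1$pairs[[1]]$rppg$values, c2$pairs[[1]]$rppg$values)
  expect_identical(c1$manifest$snr_db, c2$manifest$snr_db)
})

test_that("corruption hits the target SNR under the package's own metric", {
  for (target in c(-5, 0, 5)) {
    cfg <- synth_config(duration_s = 30, target_snr_db = target, seed = 13)
    clean <- generate_clean_pulse(cfg)
    noisy <- corrupt_to_snr(clean, cfg)
    measured <- snr_db(noisy, ref_hr = hr_series(clean))
    expect_lt(abs(measured - target), 0.5)
  }
})

test_that("a +40 dB target with white noise returns almost the clean signal", {
  cfg <- synth_config(duration_s = 30, hr_sd_bpm = 0, target_snr_db = 40,
                      noise_mix = c(1, 0, 0), seed = 6)
  clean <- generate_clean_pulse(cfg)
  noisy <- corrupt_to_snr(clean, cfg)
  # the SNR metric counts only the ~2 Hz of in-band, non-harmonic noise,
  # i.e. about a sixth of the (harmonic-notched) white noise's power at
  # fs = 25; at +40 dB the total-noise RMS is sqrt(P_harm * 1e-4 / 0.17),
  # about 2.5% of the clean RMS
  expect_lt(sqrt(mean((noisy$values - clean$values)^2)),
            0.03 * sqrt(mean(clean$values^2)))
})

test_that("unattainable SNR targets raise a configuration error", {
  cfg <- synth_config(duration_s = 30, hr_sd_bpm = 2, seed = 5)
  clean <- generate_clean_pulse(cfg)
  ceiling_db <- snr_db(clean, ref_hr = hr_series(clean))
  bad <- synth_config(duration_s = 30, hr_sd_bpm = 2,
                      target_snr_db = ceiling_db + 5, seed = 5)
  expect_error(corrupt_to_snr(clean, bad), class = "rppg_config_error")
})

test_that("the clean member of every pair is a near-perfect reference", {
  corp <- generate_corpus(5, default_config_sampler(
    duration_range_s = c(20, 20)), seed = 31)
  for (p in corp$pairs) {
    expect_gt(tmc(p$gt), 0.98)
  }
})

test_that("corpus bookkeeping matches the generated signals", {
  corp <- generate_corpus(
    90,
    default_config_sampler(snr_mean_db = 0, snr_sd_db = 0,
                           duration_range_s = c(30, 30)),
    seed = 17
  )
  s <- summary(corp$manifest)
  expect_identical(s$n_signals, 90L)
  expect_equal(s$duration_min, 45.0, tolerance = 1e-9)
  expect_lt(abs(s$snr_mean_db - 0), 0.5)

  one <- generate_corpus(1, default_config_sampler(
    duration_range_s = c(15, 15)), seed = 2)
  expect_identical(nrow(one$manifest), 1L)
  p <- one$pairs[[1]]
  expect_identical(p$rppg$fs, p$gt$fs)
  expect_identical(length(p$rppg$values), length(p$gt$values))
})

test_that("a sampled corpus reproduces the requested SNR distribution", {
  corp <- generate_corpus(
    500,
    default_config_sampler(snr_mean_db = 1.07, snr_sd_db = 4.25,
                           duration_range_s = c(30, 30)),
    seed = 23
  )
  expect_lt(abs(mean(corp$manifest$snr_db) - 1.07), 0.5)
  expect_lt(abs(sd(corp$manifest$snr_db) - 4.25), 1.0)
})
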