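# Heart-rate estimation and the four quality metrics.

test_that("hr_series nails pure tones and the window-count formula", {
  s <- sine_signal(1.2, 25, 60)
  h <- hr_series(s)
  expect_true(all(abs(h$hr - 72) < 0.1))
  # hop = round(0.5 * 25) = 13 samples; floor((1500 - 375) / 13) + 1 windows
  expect_identical(nrow(h), 87L)
  expect_true(all(diff(h$t) > 0))

  # an fs/4 tone sits exactly on a zero-padded bin
  s4 <- sine_signal(25 / 4, 25, 30, amp = 1)
  h4 <- hr_series(s4, band_hz = c(0.7, 12))
  expect_equal(unique(round(h4$hr, 3)), 60 * 25 / 4, tolerance = 1e-6)

  expect_error(hr_series(sine_signal(1.2, 25, 10)),
               class = "rppg_config_error")
})

test_that("hr_series tracks a frequency step", {
  t1 <- sin(2 * pi * 1.0 * seq(0, 30 - 1 / 25, by = 1 / 25))
  t2 <- sin(2 * pi * 2.0 * seq(0, 30 - 1 / 25, by = 1 / 25))
  s <- rppg_signal(c(t1, t2), 25)
  h <- hr_series(s)
  expect_true(all(abs(head(h$hr, 10) - 60) < 1))
  expect_true(all(abs(tail(h$hr, 10) - 120) < 1))
})

test_that("mae and pearson_r follow their definitions", {
  expect_equal(mae(c(72, 75, 80), c(70, 74, 80)), 1.0)
  expect_equal(mae(c(72, 75), c(72, 75)), 0)
  expect_equal(mae(81, 76), 5.0)
  expect_error(mae(1:3, 1:4), class = "rppg_config_error")

  hr <- c(70, 75, 80, 85)
  expect_equal(pearson_r(hr, hr), 1.0)
  expect_equal(pearson_r(hr, -hr + 10), -1.0)
  expect_error(pearson_r(hr, rep(70, 4)), class = "rppg_data_error")
  # invariance under positive affine maps
  expect_equal(pearson_r(hr, 3 * hr + 2), 1.0)
})

test_that("snr_db separates harmonic power from in-band noise", {
  pure <- sine_signal(1.2, 25, 60)
  expect_equal(snr_db(pure), 60)

  # constructed 0 dB case: in-band noise power equal to harmonic-band power
  set.seed(16)
  n <- 1500; fs <- 25
  sig <- sin(2 * pi * 1.2 * (0:(n - 1)) / fs)
  noise <- rnorm(n)
  X <- fft(noise)
  freqs <- (0:(n - 1)) * fs / n
  fmir <- pmin(freqs, fs - freqs)
  keep <- fmir >= 0.7 & fmir <= 3.5 &
    !(abs(fmir - 1.2) <= 0.2 | abs(fmir - 2.4) <= 0.2)
  X[!keep] <- 0
  shaped <- Re(fft(X, inverse = TRUE)) / n
  shaped <- shaped * sqrt(sum(sig^2) / sum(shaped^2))
  s0 <- rppg_signal(sig + shaped, fs)
  expect_lt(abs(snr_db(s0, ref_hr = 72) - 0), 0.5)

  # pure out-of-band noise barely moves the value
  oob <- 0.5 * sin(2 * pi * 0.2 * (0:(n - 1)) / fs)
  s1 <- rppg_signal(sig + shaped + oob, fs)
  expect_lt(abs(snr_db(s1, ref_hr = 72) - snr_db(s0, ref_hr = 72)), 0.1)

  expect_error(snr_db(sine_signal(1.2, 25, 5)), class = "rppg_config_error")
})

test_that("snr_db decreases monotonically with in-band noise amplitude", {
  set.seed(17)
  n <- 1500
  sig <- sin(2 * pi * 1.2 * (0:(n - 1)) / 25)
  noise <- rnorm(n)
  vals <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(a) {
    snr_db(rppg_signal(sig + a * noise, 25), ref_hr = 72)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("tmc rewards uniform pulse shapes and is scale-invariant", {
  # 75 bpm at 25 Hz: integer 20-sample period, exactly periodic on the grid
  cfg <- synth_config(duration_s = 30, hr_mean_bpm = 75, hr_sd_bpm = 0,
                      seed = 8)
  clean <- generate_clean_pulse(cfg)
  v <- tmc(clean)
  expect_gte(v, 0.999)
  scaled <- rppg_signal(13.7 * clean$values, 25)
  expect_equal(tmc(scaled), v, tolerance = 1e-12)

  # alternating two distinct shapes must score below the uniform train
  t <- (0:749) / 25
  phase <- (t %% 1.6) / 1.6
  beat_idx <- floor(t / 0.8)
  shape_a <- exp(-((t %% 0.8) - 0.2)^2 / (2 * 0.08^2))
  shape_b <- exp(-((t %% 0.8) - 0.35)^2 / (2 * 0.15^2))
  alt <- ifelse(beat_idx %% 2 == 0, shape_a, shape_b)
  v_alt <- tmc(rppg_signal(alt, 25))
  expect_lt(v_alt, v)

  set.seed(19)
  wn <- rppg_signal(rnorm(750), 25)
  res <- tryCatch(tmc(wn), rppg_data_error = function(e) NA_real_)
  expect_true(is.na(res) || res < 0.5)
})

test_that("evaluate_pair self-comparison and noise sensitivity", {
  pairs <- make_pairs(1, seed = 71, duration_s = 30)
  p <- pairs[[1]]
  rep0 <- suppressWarnings(evaluate_pair(p, p$gt))
  expect_equal(rep0$mae, 0)
  expect_true(is.na(rep0$r) || rep0$r == 1)
  expect_gte(rep0$tmc, 0.98)

  set.seed(20)
  tiny <- rppg_signal(p$gt$values + 1e-3 * sd(p$gt$values) * rnorm(750), 25)
  rep1 <- suppressWarnings(evaluate_pair(p, tiny))
  expect_lt(rep1$mae, 1)

  const <- rppg_signal(rep(0.5, 750), 25)
  expect_error(evaluate_pair(p, const), class = "rppg_data_error")
})

test_that("aggregation reports t-based confidence intervals", {
  mk <- function(mae) structure(
    list(mae = mae, r = 0.9, snr = 5, tmc = 0.9, n_windows = 10,
         subject_id = "x"), class = "quality_report")
  one <- aggregate_reports(list(mk(4)))
  expect_true(is.na(one$ci_lo[one$metric == "mae"]))

  same <- aggregate_reports(list(mk(4), mk(4), mk(4)))
  row <- same[same$metric == "mae", ]
  expect_equal(row$ci_lo, row$ci_hi)
  expect_equal(row$mean, 4)

  set.seed(21)
  many <- aggregate_reports(lapply(rnorm(100, 4, 1), mk))
  m <- many[many$metric == "mae", ]
  expect_gt(m$mean, 3.7)
  expect_lt(m$mean, 4.3)
  expect_lt(m$ci_lo, m$mean)

  expect_error(aggregate_reports(list()), class = "rppg_config_error")
})
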