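# Signal containers, CSV I/O, resampling and pair alignment.

test_that("signal construction enforces finiteness and positive rate", {
  expect_error(rppg_signal(c(1, NA, 3), 25), "position 2",
               class = "rppg_data_error")
  expect_error(rppg_signal(numeric(0), 25), class = "rppg_data_error")
  expect_error(rppg_signal(1:10, -5), class = "rppg_config_error")
  s <- rppg_signal(1:10, 25, subject_id = "a", role = "ground_truth")
  expect_s3_class(s, "rppg_signal")
  expect_equal(duration_s(s), 10 / 25)
})

test_that("write/read round-trips values, rate and metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  s <- rppg_signal(rnorm(200) * 1e3, fs = 25.5, subject_id = "subj7",
                   role = "ground_truth")
  write_signal(s, path)
  r <- read_signal(path)
  expect_identical(r$fs, s$fs)
  expect_identical(r$subject_id, "subj7")
  expect_identical(r$role, "ground_truth")
  expect_lt(max(abs(r$values - s$values) / pmax(abs(s$values), 1e-12)), 1e-9)
})

test_that("two-column CSV infers fs from the time column", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- (0:249) * 0.04
  writeLines(c("time_s,value", sprintf("%.6f,%.6f", t, sin(t))), path)
  s <- read_signal(path)
  expect_equal(s$fs, 25, tolerance = 1e-9)
  expect_length(s$values, 250)
})

test_that("value-only CSV takes fs from header or hint, else errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs=60", "value", sprintf("%.4f", sin(1:50))), path)
  expect_equal(read_signal(path)$fs, 60)

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%.4f", sin(1:50)), path2)
  expect_equal(read_signal(path2, fs_hint = 30)$fs, 30)
  expect_error(read_signal(path2), class = "rppg_config_error")
})

test_that("non-finite samples are reported with their row", {
  path <- withr::local_tempfile(fileext = ".csv")
  vals <- sprintf("%.4f", sin(1:20))
  vals[7] <- "NaN"
  writeLines(c("# fs=25", vals), path)
  expect_error(read_signal(path), "row 7", class = "rppg_data_error")
})

test_that("resampling converts rates and preserves in-band sinusoids", {
  s60 <- sine_signal(1.2, fs = 60, duration_s = 10)
  expect_length(s60$values, 600)
  r <- resample_signal(s60, 25)
  expect_equal(r$fs, 25)
  expect_length(r$values, 250)

  # identity rate is the identity map
  s <- sine_signal(1.0, fs = 25, duration_s = 10)
  expect_identical(resample_signal(s, 25)$values, s$values)

  # 1.2 Hz at 256 Hz downsampled to 25 Hz tracks the analytic sinusoid
  s256 <- sine_signal(1.2, fs = 256, duration_s = 30)
  d <- resample_signal(s256, 25)
  ref <- sin(2 * pi * 1.2 * (seq_along(d$values) - 1) / 25)
  expect_gt(cor(d$values, ref), 0.999)

  expect_error(resample_signal(s, 0.001), class = "rppg_config_error")
})

test_that("align_pair resamples to a common rate and truncates", {
  r <- sine_signal(1.2, fs = 25, duration_s = 30)
  g <- sine_signal(1.2, fs = 60, duration_s = 30)
  g$role <- "ground_truth"
  p <- align_pair(r, g, target_fs = 25)
  expect_equal(p$rppg$fs, 25)
  expect_length(p$gt$values, 750)
  expect_length(p$rppg$values, 750)

  # shorter member rules the common length
  g2 <- sine_signal(1.2, fs = 60, duration_s = 28)
  p2 <- align_pair(r, g2, target_fs = 25)
  expect_length(p2$rppg$values, 700)
})

test_that("align_pair invariants hold over randomized lengths and rates", {
  set.seed(42)
  for (i in 1:20) {
    fs_r <- sample(c(20, 25, 30, 60), 1)
    fs_g <- sample(c(25, 60, 256), 1)
    dur_r <- runif(1, 5, 20)
    dur_g <- runif(1, 5, 20)
    r <- sine_signal(1.0, fs = fs_r, duration_s = dur_r)
    g <- sine_signal(1.0, fs = fs_g, duration_s = dur_g)
    p <- align_pair(r, g, target_fs = 25)
    expect_identical(p$rppg$fs, p$gt$fs)
    expect_identical(length(p$rppg$values), length(p$gt$values))
  }
})

test_that("corpus round-trips through a directory", {
  corp <- generate_corpus(
    2, default_config_sampler(duration_range_s = c(12, 12)), seed = 5)
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus(dir)
  expect_equal(nrow(back$manifest), 2)
  expect_equal(back$pairs[[1]]$rppg$values, corp$pairs[[1]]$rppg$values,
               tolerance = 1e-9)
  s <- summary(back$manifest)
  expect_equal(s$duration_min, 2 * 12 / 60, tolerance = 1e-6)
})
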