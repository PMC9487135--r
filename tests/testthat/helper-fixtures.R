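# Shared fixtures, all built in code.

sine_signal <- function(freq_hz, fs = 25, duration_s = 60, amp = 1,
                        subject_id = "sine") {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  rppg_signal(amp * sin(2 * pi * freq_hz * t), fs, subject_id = subject_id)
}

# A small preprocessed corpus of aligned pairs at a fixed target SNR.
make_pairs <- function(n, seed, duration_s = 20, snr_db = 0) {
  corp <- generate_corpus(
    n,
    default_config_sampler(snr_mean_db = snr_db, snr_sd_db = 0,
                           duration_range_s = c(duration_s, duration_s)),
    seed = seed
  )
  lapply(corp$pairs, preprocess_pair)
}

# Synthetic manifest rows without generating any signals (for split tests).
fake_manifest <- function(n, seed = 1, snr_mean = 1, snr_sd = 4) {
  set.seed(seed)
  corpus_manifest(data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    rppg_path = NA_character_, gt_path = NA_character_,
    duration_s = rep(30, n),
    snr_db = rnorm(n, snr_mean, snr_sd),
    stringsAsFactors = FALSE
  ))
}

expect_rppg_error <- function(expr, class) {
  expect_error(expr, class = class)
}
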