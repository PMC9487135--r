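# Heart-rate estimation and the four signal-quality metrics: window-wise
# heart-rate MAE, Pearson r, harmonic-band SNR, and template match
# correlation (TMC).

#' Windowed FFT heart-rate estimation
#'
#' Slides a window over the signal (15 s with a 0.5-s step by default); each
#' window is mean-subtracted, Hann-tapered, zero-padded to an `nfft`-point
#' spectrum and the in-band magnitude peak is reported in beats per minute.
#'
#' @param ts An [rppg_signal].
#' @param window_s Analysis window length in seconds.
#' @param step_s Window step in seconds (the hop is `round(step_s * fs)`
#'   samples; true window-center times are reported).
#' @param band_hz Search band in Hz, default 0.7-3.5 (42-210 bpm).
#' @param nfft Zero-padded spectrum length (>= 2^16 gives < 0.025 bpm
#'   resolution at 25 Hz).
#'
#' @return An object of class `hr_series`: a data frame with columns `t`
#'   (window centers, s) and `hr` (bpm).
#' @examples
#' s <- rppg_signal(sin(2 * pi * 1.2 * seq(0, 60, by = 1 / 25)), fs = 25)
#' head(hr_series(s))  # 72 bpm in every window
#' @export
hr_series <- function(ts, window_s = 15, step_s = 0.5,
                      band_hz = c(0.7, 3.5), nfft = 2L^16L) {
  stopifnot(inherits(ts, "rppg_signal"))
  fs <- ts$fs
  w <- round(window_s * fs)
  if (length(ts$values) < w)
    stop_config("signal shorter (", length(ts$values),
                ") than one analysis window (", w, " samples)")
  # round-half-up so a 0.5-s step at 25 Hz (12.5 samples) hops 13 samples
  hop <- max(1L, floor(step_s * fs + 0.5))
  nfft <- max(nfft, 2^ceiling(log2(w)))
  taper <- hann_window(w)
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  in_band <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (length(in_band) == 0L) stop_data("empty in-band spectrum")

  starts <- seq(1L, length(ts$values) - w + 1L, by = hop)
  hr <- vapply(starts, function(s0) {
    x <- ts$values[s0:(s0 + w - 1L)]
    x <- (x - mean(x)) * taper
    p <- Mod(fft(c(x, numeric(nfft - w))))[in_band]
    if (max(p) <= 0) stop_data("window has no spectral content")
    60 * freqs[in_band[which.max(p)]]
  }, numeric(1))

  structure(
    data.frame(t = (starts - 1L + (w - 1) / 2) / fs, hr = hr),
    class = c("hr_series", "data.frame"),
    fs = fs, window_s = window_s, step_s = step_s, band_hz = band_hz
  )
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

as_hr_vector <- function(x) {
  if (inherits(x, "hr_series")) x$hr else as.numeric(x)
}

#' Mean absolute heart-rate error (bpm)
#'
#' Window-wise mean absolute difference between heart rates estimated from
#' the evaluated signal and from the contact ground truth.
#'
#' @param hr,hc [hr_series] objects (or bare bpm vectors) of equal length.
#' @return MAE in bpm.
#' @export
mae <- function(hr, hc) {
  a <- as_hr_vector(hr)
  b <- as_hr_vector(hc)
  if (length(a) != length(b) || length(a) < 1L)
    stop_config("heart-rate series must have equal, positive length")
  mean(abs(a - b))
}

#' Pearson correlation between heart-rate series
#'
#' Standard product-moment correlation; +1 means total positive linear
#' agreement between estimated and reference heart rate.
#'
#' @param hr,hc [hr_series] objects (or bare bpm vectors) of equal length
#'   (>= 2), neither constant.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(hr, hc) {
  a <- as_hr_vector(hr)
  b <- as_hr_vector(hc)
  if (length(a) != length(b) || length(a) < 2L)
    stop_config("heart-rate series must have equal length >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop_data("correlation undefined for a constant heart-rate series")
  cor(a, b)
}

#' Harmonic-band signal-to-noise ratio (dB)
#'
#' Computed on the full-length spectrum: signal power is the in-band power
#' within `harmonic_halfwidth_hz` of the heart-rate fundamental and its
#' second harmonic; noise power is the remaining in-band power.  The
#' fundamental comes from `ref_hr` when given (an [hr_series], whose median
#' is used, or a single bpm value), else from the in-band spectral peak of
#' the signal itself.
#'
#' @param ts An [rppg_signal] of at least 10 s.
#' @param ref_hr Optional reference heart rate ([hr_series] or bpm scalar).
#' @param band_hz Analysis band in Hz.
#' @param harmonic_halfwidth_hz Half-width of the two signal bands in Hz.
#' @param clamp_db Symmetric output clamp, needed for noiseless synthetic
#'   inputs whose noise power underflows.
#' @return SNR in dB, clamped to `[-clamp_db, clamp_db]`.
#' @export
snr_db <- function(ts, ref_hr = NULL, band_hz = c(0.7, 3.5),
                   harmonic_halfwidth_hz = 0.2, clamp_db = 60) {
  stopifnot(inherits(ts, "rppg_signal"))
  n <- length(ts$values)
  if (n < 10 * ts$fs)
    stop_config("snr_db needs at least 10 s of signal")
  x <- ts$values - mean(ts$values)
  p <- Mod(fft(x))^2
  half <- floor(n / 2) + 1L
  freqs <- (seq_len(half) - 1L) * ts$fs / n
  p <- p[seq_len(half)]
  in_band <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(in_band)) stop_data("empty in-band spectrum")

  f0 <- if (is.null(ref_hr)) {
    if (max(p[in_band]) <= 0) stop_data("signal has no in-band power")
    freqs[in_band][which.max(p[in_band])]
  } else {
    median(as_hr_vector(ref_hr)) / 60
  }

  harmonic <- (abs(freqs - f0) <= harmonic_halfwidth_hz) |
    (abs(freqs - 2 * f0) <= harmonic_halfwidth_hz)
  sig_mask <- in_band & harmonic
  noise_mask <- in_band & !harmonic
  p_sig <- sum(p[sig_mask])
  p_noise <- sum(p[noise_mask])
  if (p_noise <= 0) return(clamp_db)
  if (p_sig <= 0) return(-clamp_db)
  max(-clamp_db, min(clamp_db, 10 * log10(p_sig / p_noise)))
}

# Local maxima with topographic prominence, largest-first minimum-distance
# pruning.  Returns sorted peak indices.
find_pulse_peaks <- function(x, min_distance, min_prominence) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    # walk left/right until a strictly higher sample; prominence is the
    # height above the higher of the two interval minima
    left_min <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      left_min <- min(left_min, x[j])
      j <- j - 1L
    }
    if (j < 1L) left_min <- min(x[seq_len(i)])
    right_min <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      right_min <- min(right_min, x[j])
      j <- j + 1L
    }
    if (j > n) right_min <- min(x[i:n])
    x[i] - max(left_min, right_min)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0L) return(integer(0))
  # greedy pruning: keep taller peaks, drop neighbours closer than min_distance
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_distance)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Template match correlation
#'
#' Pulse-shape-uniformity index: (1) detect pulse peaks (minimum spacing
#' `min_peak_distance_s`, prominence at least `min_prominence_frac` of the
#' signal's standard deviation); (2) take the median beat-to-beat interval
#' `m`; (3) extract an `m`-wide segment centered on each peak, discarding
#' peaks whose segment would overrun the record; (4) average the segments
#' into a template; (5) return the mean Pearson correlation of the segments
#' with the template.  Values near 1 indicate a uniform pulse shape.
#'
#' @param ts An [rppg_signal].
#' @param min_peak_distance_s Minimum inter-peak spacing in seconds
#'   (0.33 s allows rates up to about 182 bpm).
#' @param min_prominence_frac Peak prominence threshold as a fraction of
#'   `sd(ts)`.
#' @return TMC in [-1, 1].
#' @export
tmc <- function(ts, min_peak_distance_s = 0.33, min_prominence_frac = 0.3) {
  stopifnot(inherits(ts, "rppg_signal"))
  x <- ts$values
  if (sd(x) == 0) stop_data("insufficient pulses: constant signal")
  peaks <- find_pulse_peaks(
    x,
    min_distance = min_peak_distance_s * ts$fs,
    min_prominence = min_prominence_frac * sd(x)
  )
  if (length(peaks) < 3L) stop_data("insufficient pulses: ",
                                    length(peaks), " peaks detected")
  m <- round(median(diff(peaks)))
  half <- floor(m / 2)
  len <- 2L * half + 1L
  segs <- lapply(peaks, function(p) {
    if (p - half < 1L || p + half > length(x)) NULL
    else x[(p - half):(p + half)]
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) < 3L) stop_data("insufficient pulses: ",
                                   length(segs), " full segments")
  segmat <- do.call(cbind, segs)
  template <- rowMeans(segmat)
  if (sd(template) == 0) stop_data("degenerate pulse template")
  mean(apply(segmat, 2L, function(s) {
    if (sd(s) == 0) 0 else cor(s, template)
  }))
}

#' Evaluate a filtered signal against its recording pair
#'
#' Computes the four quality metrics for one recording: heart-rate MAE and
#' Pearson r between [hr_series()] of the filtered signal and of the ground
#' truth, [snr_db()] of the filtered signal referenced to the ground-truth
#' heart rate, and [tmc()] of the filtered signal.
#'
#' If either heart-rate series is constant (possible on perfectly steady
#' synthetic pulses) `r` is reported as `NA` with a warning rather than
#' failing the whole evaluation.
#'
#' @param pair The preprocessed [signal_pair].
#' @param filtered The filtered [rppg_signal], aligned with `pair`.
#' @param ... Passed on to [hr_series()].
#' @return An object of class `quality_report`: list with `mae`, `r`, `snr`,
#'   `tmc`, `n_windows`, `subject_id`.
#' @export
evaluate_pair <- function(pair, filtered, ...) {
  stopifnot(inherits(pair, "signal_pair"), inherits(filtered, "rppg_signal"))
  if (length(filtered$values) != length(pair$gt$values))
    stop_config("filtered signal is not aligned with the pair")
  hc <- hr_series(pair$gt, ...)
  hr <- hr_series(filtered, ...)
  r <- tryCatch(pearson_r(hr, hc), rppg_data_error = function(e) {
    warning("pearson_r undefined (constant heart-rate series); returning NA",
            call. = FALSE)
    NA_real_
  })
  structure(
    list(
      mae = mae(hr, hc),
      r = r,
      snr = snr_db(filtered, ref_hr = hc),
      tmc = tmc(filtered),
      n_windows = nrow(hr),
      subject_id = filtered$subject_id
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> %s: MAE %.2f bpm, r %.3f, SNR %.2f dB, TMC %.3f (%d windows)\n",
    x$subject_id, x$mae, x$r, x$snr, x$tmc, x$n_windows))
  invisible(x)
}

#' Aggregate quality reports over a corpus
#'
#' Per-metric mean with a t-based 95% confidence interval over per-signal
#' values.  With a single report the CI is reported as `NA`.
#'
#' @param reports List of `quality_report` objects.
#' @param conf Confidence level.
#' @return A data frame (class `quality_summary`) with one row per metric:
#'   `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
aggregate_reports <- function(reports, conf = 0.95) {
  if (length(reports) < 1L) stop_config("no reports to aggregate")
  stopifnot(all(vapply(reports, inherits, logical(1), "quality_report")))
  metrics <- c("mae", "r", "snr", "tmc")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]] %||% NA_real_, numeric(1))
    v <- v[!is.na(v)]
    n <- length(v)
    mu <- if (n > 0) mean(v) else NA_real_
    half <- if (n > 1 && sd(v) > 0)
      qt(1 - (1 - conf) / 2, n - 1) * sd(v) / sqrt(n)
    else if (n > 1) 0 else NA_real_
    data.frame(metric = m, mean = mu, ci_lo = mu - half, ci_hi = mu + half,
               n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("quality_summary", "data.frame")
  out
}
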