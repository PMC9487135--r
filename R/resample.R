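# Band-limited resampling and pair alignment.

# Fourier-domain resampling: the spectrum is truncated (downsampling) or
# zero-padded (upsampling) and inverted on the new grid.  Exact for in-band
# content; edge behaviour is the usual periodic-extension assumption.
fourier_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  keep <- floor(min(n, n_out) / 2)
  Y[1L] <- X[1L]
  if (keep >= 1L) {
    Y[2L:(keep + 1L)] <- X[2L:(keep + 1L)]
    Y[(n_out - keep + 1L):n_out] <- X[(n - keep + 1L):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Resample a signal to a new rate
#'
#' Band-limited (Fourier) resampling: spectral content below the new Nyquist
#' rate is preserved exactly, so in-band cardiac components survive rate
#' conversion without phase distortion.  At the identity rate the samples are
#' returned unchanged.
#'
#' @param ts An [rppg_signal].
#' @param target_fs Target sampling rate in Hz.
#' @return An [rppg_signal] at `target_fs` with
#'   `round(length(ts) * target_fs / fs)` samples.
#' @examples
#' s <- rppg_signal(sin(2 * pi * 1.2 * seq(0, 20, by = 1 / 60)), fs = 60)
#' length(resample_signal(s, 25))
#' @export
resample_signal <- function(ts, target_fs) {
  stopifnot(inherits(ts, "rppg_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop_config("target_fs must be a single positive number")
  n_out <- round(length(ts$values) * target_fs / ts$fs)
  if (n_out < 2L)
    stop_config("target_fs ", target_fs, " Hz leaves fewer than 2 samples")
  if (isTRUE(all.equal(target_fs, ts$fs))) {
    return(replace_values(ts, ts$values, fs = target_fs))
  }
  replace_values(ts, fourier_resample(ts$values, n_out), fs = target_fs)
}

#' Align an rPPG trace with its ground-truth waveform
#'
#' Resamples both signals to a common rate (25 Hz by default, the working
#' rate of the whole pipeline) and truncates them to the shorter common
#' length, counted from the first sample.  No cross-correlation lag search is
#' attempted: recordings are assumed to start synchronously.
#'
#' @param rppg The camera-derived trace ([rppg_signal], role `"rppg"`).
#' @param gt The contact ground truth ([rppg_signal], role `"ground_truth"`).
#' @param target_fs Common sampling rate in Hz.
#' @return A [signal_pair] at `target_fs`.
#' @export
align_pair <- function(rppg, gt, target_fs = 25) {
  stopifnot(inherits(rppg, "rppg_signal"), inherits(gt, "rppg_signal"))
  r <- resample_signal(rppg, target_fs)
  g <- resample_signal(gt, target_fs)
  n <- min(length(r$values), length(g$values))
  if (n < 1L) stop_data("signals have no overlapping support")
  r <- replace_values(r, r$values[seq_len(n)])
  g <- replace_values(g, g$values[seq_len(n)])
  signal_pair(r, g, meta = list(duration_s = n / target_fs))
}
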