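# The three classical filters the deep filter is compared against:
# zero-phase Butterworth bandpass, wavelet sub-band denoising, and
# Savitzky-Golay smoothing.

#' Zero-phase Butterworth bandpass filter
#'
#' Order-`order` Butterworth design applied forward and backward
#' (`signal::filtfilt`), so the passband is squared and the phase is zero --
#' pulse peak timing is preserved.  Defaults pass the 0.7-3.5 Hz
#' (42-210 bpm) cardiac band.
#'
#' @param ts An [rppg_signal].
#' @param lo_hz,hi_hz Cutoff frequencies in Hz (`lo < hi < fs/2`).
#' @param order Butterworth design order.
#' @return The filtered [rppg_signal] (length preserved).
#' @export
bandpass <- function(ts, lo_hz = 0.7, hi_hz = 3.5, order = 4L) {
  stopifnot(inherits(ts, "rppg_signal"))
  nyq <- ts$fs / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < nyq))
    stop_config("need 0 < lo_hz < hi_hz < fs/2 (Nyquist ", nyq, " Hz)")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  replace_values(ts, signal::filtfilt(bf, ts$values))
}

# Daubechies-4 (8-tap) scaling filter; wavelet filter by quadrature mirror.
DB4_SCALING <- c(
  0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
  -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
  0.032883011666982945, -0.010597401784997278
)

db4_filters <- function() {
  g <- DB4_SCALING
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(g = g, h = h)
}

# Maximal-overlap (undecimated) DWT with periodic boundary, via FFT-based
# circular convolution with filters upsampled by 2^(j-1).  Length-preserving
# for any n and exactly invertible, which is what a linear sub-band-zeroing
# denoiser needs.
modwt_filter_fft <- function(filt, level, n) {
  f <- numeric(n)
  idx <- (seq_along(filt) - 1L) * 2L^(level - 1L)
  if (max(idx) >= n) stop_config("signal too short for wavelet level ", level)
  f[idx %% n + 1L] <- f[idx %% n + 1L] + filt / sqrt(2)
  fft(f)
}

modwt_db4 <- function(x, levels) {
  n <- length(x)
  fl <- db4_filters()
  W <- vector("list", levels)
  V <- fft(x)
  for (j in seq_len(levels)) {
    Gf <- modwt_filter_fft(fl$g, j, n)
    Hf <- modwt_filter_fft(fl$h, j, n)
    W[[j]] <- V * Hf
    V <- V * Gf
  }
  list(W = W, V = V, n = n, levels = levels)
}

imodwt_db4 <- function(dec) {
  n <- dec$n
  fl <- db4_filters()
  V <- dec$V
  for (j in rev(seq_len(dec$levels))) {
    Gf <- modwt_filter_fft(fl$g, j, n)
    Hf <- modwt_filter_fft(fl$h, j, n)
    V <- V * Conj(Gf) + dec$W[[j]] * Conj(Hf)
  }
  Re(fft(V, inverse = TRUE)) / n
}

#' Wavelet sub-band denoising
#'
#' Maximal-overlap discrete wavelet transform (Daubechies-4, periodic
#' boundary) to `levels` levels; detail sub-bands listed in `keep_levels`
#' are retained and every other coefficient band (including the final
#' approximation) is zeroed before reconstruction.  At 25 Hz the default
#' retains details 3 and 4, whose nominal pass bands (1.56-3.13 and
#' 0.78-1.56 Hz) jointly cover the cardiac band.  The transform is linear
#' and length-preserving.
#'
#' @param ts An [rppg_signal].
#' @param levels Decomposition depth.
#' @param keep_levels Detail levels to retain.
#' @return The denoised [rppg_signal].
#' @export
wavelet_denoise <- function(ts, levels = 4L, keep_levels = c(3L, 4L)) {
  stopifnot(inherits(ts, "rppg_signal"))
  if (length(ts$values) < 2L^levels)
    stop_config("signal too short (", length(ts$values),
                ") for ", levels, " wavelet levels")
  if (any(keep_levels > levels)) stop_config("keep_levels exceed depth")
  dec <- modwt_db4(ts$values, levels)
  for (j in seq_len(levels)) {
    if (!(j %in% keep_levels)) dec$W[[j]][] <- 0
  }
  dec$V[] <- 0  # drop the approximation (baseline) band
  replace_values(ts, imodwt_db4(dec))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (`signal::sgolayfilt`); with the
#' default 9-sample window and order 2 any quadratic signal is reproduced
#' exactly.
#'
#' @param ts An [rppg_signal].
#' @param window_samples Odd window length.
#' @param polyorder Polynomial order (`< window_samples`).
#' @return The smoothed [rppg_signal].
#' @export
savgol <- function(ts, window_samples = 9L, polyorder = 2L) {
  stopifnot(inherits(ts, "rppg_signal"))
  if (window_samples %% 2L == 0L || polyorder >= window_samples)
    stop_config("need an odd window and polyorder < window")
  replace_values(ts,
                 signal::sgolayfilt(ts$values, p = polyorder,
                                    n = window_samples))
}
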