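# The normalization chain applied to every signal before filtering or
# training: resample -> (ground truth only: smooth) -> detrend -> scale to
# [-1, 1].  Normalization comes last so the training range is guaranteed.

#' Remove slow baseline trends
#'
#' Subtracts a centered moving-average trend.  The default 2-s window passes
#' the 0.7-3.5 Hz cardiac band (with a predictable, mild attenuation given by
#' the Dirichlet kernel of the averager) while removing DC and slow
#' illumination drift.  Edge windows shrink symmetrically, so the output has
#' the input's length.
#'
#' @param ts An [rppg_signal].
#' @param trend_window_s Trend window width in seconds.
#' @return The detrended [rppg_signal].
#' @export
detrend <- function(ts, trend_window_s = 2.0) {
  stopifnot(inherits(ts, "rppg_signal"))
  width <- round(trend_window_s * ts$fs)
  if (length(ts$values) <= width)
    stop_config("signal (", length(ts$values),
                " samples) not longer than trend window (", width, ")")
  replace_values(ts, ts$values - moving_average(ts$values, width))
}

#' Scale a signal to the exact range [-1, 1]
#'
#' Affine map `2 * (x - min) / (max - min) - 1`; the output attains -1 and
#' +1 exactly.  Constant signals cannot be scaled and raise a
#' degenerate-input error.
#'
#' @param ts An [rppg_signal].
#' @return The rescaled [rppg_signal].
#' @export
normalize_unit_range <- function(ts) {
  stopifnot(inherits(ts, "rppg_signal"))
  lo <- min(ts$values)
  hi <- max(ts$values)
  if (hi <= lo)
    stop_data("constant signal cannot be normalized to [-1, 1]")
  replace_values(ts, 2 * (ts$values - lo) / (hi - lo) - 1)
}

#' Smooth a ground-truth waveform
#'
#' Centered moving-average smoothing, applied to contact BVP references to
#' suppress sensor quantization before they are used as regression targets.
#' Length-preserving (edge windows shrink).
#'
#' @param ts An [rppg_signal].
#' @param window_samples Odd window width in samples (>= 3).
#' @return The smoothed [rppg_signal].
#' @export
smooth_reference <- function(ts, window_samples = 5L) {
  stopifnot(inherits(ts, "rppg_signal"))
  if (window_samples < 3L || window_samples %% 2L == 0L)
    stop_config("window_samples must be odd and >= 3")
  replace_values(ts, moving_average(ts$values, window_samples))
}

#' Preprocess a recording pair for training or evaluation
#'
#' Fixed order: both members are resampled to `target_fs`; the ground truth
#' is smoothed; both are detrended and scaled to exactly `[-1, 1]`.
#' Normalization is per whole signal (not per window), so window amplitudes
#' retain their relative size within a recording.
#'
#' @param pair A [signal_pair].
#' @param target_fs Working sampling rate in Hz.
#' @param trend_window_s Detrending window in seconds.
#' @param smooth_window Ground-truth smoothing window in samples (odd).
#' @return The preprocessed [signal_pair].
#' @export
preprocess_pair <- function(pair, target_fs = 25, trend_window_s = 2.0,
                            smooth_window = 5L) {
  stopifnot(inherits(pair, "signal_pair"))
  r <- resample_signal(pair$rppg, target_fs)
  g <- resample_signal(pair$gt, target_fs)
  g <- smooth_reference(g, smooth_window)
  r <- normalize_unit_range(detrend(r, trend_window_s))
  g <- normalize_unit_range(detrend(g, trend_window_s))
  signal_pair(r, g, meta = c(pair$meta, list(preprocessed = TRUE)))
}
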