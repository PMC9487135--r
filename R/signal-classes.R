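#' Uniformly sampled physiological signal
#'
#' The basic container every other function in the package consumes: a 1-D
#' vector of samples with a sampling rate, a subject identifier and a role
#' tag distinguishing camera-derived rPPG traces from contact ground-truth
#' blood-volume-pulse (BVP) waveforms.
#'
#' @param values Numeric vector of samples (arbitrary units). Must be finite
#'   and non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Opaque subject/recording identifier.
#' @param role Either `"rppg"` or `"ground_truth"`.
#'
#' @return An object of class `rppg_signal`: a list with elements `values`,
#'   `fs`, `subject_id` and `role`.
#' @examples
#' s <- rppg_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 25)), fs = 25)
#' duration_s(s)
#' @export
rppg_signal <- function(values, fs, subject_id = "unknown",
                        role = c("rppg", "ground_truth")) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (length(values) < 1L) stop_data("signal must contain at least one sample")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop_data("non-finite sample at position ", bad)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_config("fs must be a single positive number")
  structure(
    list(values = values, fs = as.numeric(fs),
         subject_id = as.character(subject_id), role = role),
    class = "rppg_signal"
  )
}

#' @export
print.rppg_signal <- function(x, ...) {
  cat(sprintf("<rppg_signal> %s [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$role, length(x$values), x$fs,
              length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.rppg_signal <- function(x) length(x$values)

#' Signal duration in seconds
#' @param ts An [rppg_signal].
#' @return Duration in seconds.
#' @export
duration_s <- function(ts) {
  stopifnot(inherits(ts, "rppg_signal"))
  length(ts$values) / ts$fs
}

# Re-wrap a signal with new samples, keeping metadata.
replace_values <- function(ts, values, fs = ts$fs) {
  rppg_signal(values, fs, subject_id = ts$subject_id, role = ts$role)
}

#' Aligned rPPG / ground-truth recording pair
#'
#' The unit of training and evaluation: one camera-derived rPPG trace and the
#' simultaneous contact BVP waveform, sharing a sampling rate and length.
#'
#' @param rppg An [rppg_signal] with role `"rppg"`.
#' @param gt An [rppg_signal] with role `"ground_truth"`.
#' @param meta Optional named list of free-form annotations.
#'
#' @return An object of class `signal_pair`.
#' @seealso [align_pair()] to build a pair from signals at different rates.
#' @export
signal_pair <- function(rppg, gt, meta = list()) {
  stopifnot(inherits(rppg, "rppg_signal"), inherits(gt, "rppg_signal"))
  if (!isTRUE(all.equal(rppg$fs, gt$fs)))
    stop_data("pair members must share a sampling rate (",
              rppg$fs, " vs ", gt$fs, " Hz)")
  if (length(rppg$values) != length(gt$values))
    stop_data("pair members must share a length (",
              length(rppg$values), " vs ", length(gt$values), ")")
  structure(list(rppg = rppg, gt = gt, meta = meta), class = "signal_pair")
}

#' @export
print.signal_pair <- function(x, ...) {
  cat(sprintf("<signal_pair> %s: %d samples @ %g Hz (%.1f s)\n",
              x$rppg$subject_id, length(x$rppg$values), x$rppg$fs,
              duration_s(x$rppg)))
  invisible(x)
}

#' Corpus manifest
#'
#' Per-signal bookkeeping for a corpus: subject identifier, optional file
#' paths, duration and measured SNR, plus a corpus-level summary (signal
#' count, total duration in minutes, mean and sd of SNR in dB).
#'
#' @param entries A data frame with columns `subject_id`, `rppg_path`,
#'   `gt_path`, `duration_s`, `snr_db`.
#'
#' @return An object of class `corpus_manifest` (a data frame).
#' @export
corpus_manifest <- function(entries) {
  req <- c("subject_id", "rppg_path", "gt_path", "duration_s", "snr_db")
  if (!all(req %in% names(entries)))
    stop_config("manifest requires columns: ", paste(req, collapse = ", "))
  if (any(!nzchar(entries$subject_id)))
    stop_data("manifest contains empty subject ids")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  class(entries) <- c("corpus_manifest", "data.frame")
  entries
}

#' Summarise a corpus manifest
#'
#' @param object A [corpus_manifest].
#' @param ... Unused.
#' @return A list with `n_signals`, `duration_min`, `snr_mean_db`,
#'   `snr_sd_db`.
#' @export
summary.corpus_manifest <- function(object, ...) {
  list(
    n_signals = nrow(object),
    duration_min = sum(object$duration_s) / 60,
    snr_mean_db = mean(object$snr_db),
    snr_sd_db = if (nrow(object) > 1L) sd(object$snr_db) else NA_real_
  )
}

#' @export
print.corpus_manifest <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<corpus_manifest> %d signals, %.1f min total, SNR %.2f +/- %.2f dB\n",
    s$n_signals, s$duration_min, s$snr_mean_db, s$snr_sd_db))
  invisible(x)
}
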