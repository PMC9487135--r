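# Sliding-window construction: the design matrix Y and target structure G
# fed to the sequence model.

#' Extract sliding windows from a signal
#'
#' Windows start at samples `1, 1 + stride, 1 + 2 * stride, ...`; the count
#' is `floor((T - L) / stride) + 1`.
#'
#' @param ts An [rppg_signal] (or bare numeric vector).
#' @param L Window length in samples.
#' @param stride Window step in samples.
#' @return A `count x L` numeric matrix, one window per row.
#' @export
build_windows <- function(ts, L, stride = 1L) {
  x <- if (inherits(ts, "rppg_signal")) ts$values else as.numeric(ts)
  n <- length(x)
  if (L > n) stop_config("window length L = ", L,
                         " exceeds signal length ", n)
  if (stride < 1L) stop_config("stride must be >= 1")
  starts <- seq.int(1L, n - L + 1L, by = stride)
  out <- matrix(0, nrow = length(starts), ncol = L)
  for (k in seq_along(starts)) {
    out[k, ] <- x[starts[k]:(starts[k] + L - 1L)]
  }
  out
}

#' Build the training window set from recording pairs
#'
#' Many-to-one (`"mto"`): each input row is an `L`-sample rPPG window and
#' its target is the *next* ground-truth sample -- the model forecasts the
#' clean sample following the window.  Many-to-many (`"mtm"`): each input
#' row is an `L`-sample rPPG window and the target is the time-aligned
#' `L`-sample ground-truth window.  Rows from all pairs are concatenated.
#'
#' @param pairs List of preprocessed [signal_pair] objects.
#' @param approach `"mto"` or `"mtm"`.
#' @param cfg A [train_config]; `L` and `stride` are used.
#' @return An object of class `window_set`: list with `Y` (inputs, W x L),
#'   `G` (targets: length-W vector for MTO, W x L matrix for MTM), `L`,
#'   `stride`, `approach`.
#' @export
build_training_set <- function(pairs, approach = c("mtm", "mto"),
                               cfg = train_config()) {
  approach <- match.arg(approach)
  if (length(pairs) == 0L) stop_config("empty pair list")
  stopifnot(all(vapply(pairs, inherits, logical(1), "signal_pair")))
  L <- cfg$L
  stride <- cfg$stride
  L_eff <- if (approach == "mto") L + 1L else L
  Ys <- list()
  Gs <- list()
  for (p in pairs) {
    n <- length(p$rppg$values)
    if (n < L_eff)
      stop_config("signal ", p$rppg$subject_id, " shorter (", n,
                  ") than required window span (", L_eff, ")")
    starts <- seq.int(1L, n - L_eff + 1L, by = stride)
    Yi <- matrix(0, nrow = length(starts), ncol = L)
    for (k in seq_along(starts))
      Yi[k, ] <- p$rppg$values[starts[k]:(starts[k] + L - 1L)]
    Ys[[length(Ys) + 1L]] <- Yi
    if (approach == "mto") {
      Gs[[length(Gs) + 1L]] <- p$gt$values[starts + L]
    } else {
      Gi <- matrix(0, nrow = length(starts), ncol = L)
      for (k in seq_along(starts))
        Gi[k, ] <- p$gt$values[starts[k]:(starts[k] + L - 1L)]
      Gs[[length(Gs) + 1L]] <- Gi
    }
  }
  Y <- do.call(rbind, Ys)
  G <- if (approach == "mto") unlist(Gs) else do.call(rbind, Gs)
  structure(list(Y = Y, G = G, L = L, stride = stride, approach = approach),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s: %d windows of length %d (stride %d)\n",
              x$approach, nrow(x$Y), x$L, x$stride))
  invisible(x)
}
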