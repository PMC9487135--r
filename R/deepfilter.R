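# The LSTM deep filter: configuration, model construction (Glorot-uniform
# initialization), minibatch Adam training under a staged learning-rate
# schedule, and the two inference modes -- many-to-one next-sample
# forecasting with input passthrough over the first L samples, and
# many-to-many windowed denoising recombined by overlap-add.

#' Training configuration for the deep filter
#'
#' Defaults are the reference training recipe: 100 epochs, batch 32, three
#' 125-unit LSTM layers, 5-s windows (125 samples at 25 Hz), dropout 0.2 on
#' the first two layers, and a staged Adam learning rate of 0.002 (epochs
#' 1-10), 0.001 (11-20), 0.0005 (21-50) and 0.0001 thereafter.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr_schedule Data frame with columns `from`, `to`, `rate`; rates
#'   must be positive and non-increasing across ranges.
#' @param dropout Dropout fraction applied to the outputs of the first two
#'   recurrent layers during training.
#' @param units LSTM units per layer.
#' @param L Window length in samples.
#' @param stride Training window stride in samples (1 reproduces the
#'   reference setup; larger strides thin the window set for quick runs).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L,
                         lr_schedule = data.frame(
                           from = c(1L, 11L, 21L, 51L),
                           to = c(10L, 20L, 50L, Inf),
                           rate = c(2e-3, 1e-3, 5e-4, 1e-4)),
                         dropout = 0.2, units = 125L, L = 125L,
                         stride = 1L, seed = 1L) {
  if (L < 2L) stop_config("L must be >= 2")
  if (any(lr_schedule$rate <= 0) || is.unsorted(rev(lr_schedule$rate)))
    stop_config("learning rates must be positive and non-increasing")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must lie in [0, 1)")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr_schedule = lr_schedule, dropout = dropout,
         units = as.integer(units), L = as.integer(L),
         stride = as.integer(stride), seed = as.integer(seed)),
    class = "train_config"
  )
}

glorot_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_params <- function(units, seed) {
  with_seed(seed, {
    mk_layer <- function(input_dim) {
      b <- rep(0, 4 * units)
      b[(units + 1):(2 * units)] <- 1  # forget-gate bias starts open
      list(W = glorot_uniform(input_dim, 4 * units),
           U = glorot_uniform(units, 4 * units),
           b = b)
    }
    l1 <- mk_layer(1L)
    l2 <- mk_layer(units)
    l3 <- mk_layer(units)
    list(l1$W, l1$U, l1$b, l2$W, l2$U, l2$b, l3$W, l3$U, l3$b,
         glorot_uniform(units, 1L), 0)
  })
}

#' Build an (untrained) LSTM deep-filter model
#'
#' Three stacked LSTM layers of `cfg$units` units with tanh activations and
#' a single linear output unit.  The many-to-one head reads the final
#' hidden state (return-sequences T/T/F); the many-to-many head reads every
#' timestep (T/T/T), emitting one denoised sample per input sample.
#' Parameters are Glorot-uniform initialized under `cfg$seed`; the forget
#' gate bias starts at 1.
#'
#' @param approach `"mto"` or `"mtm"`.
#' @param cfg A [train_config].
#' @return An object of class `deep_filter`.
#' @export
build_model <- function(approach = c("mtm", "mto"), cfg = train_config()) {
  approach <- match.arg(approach)
  structure(
    list(approach = approach, L = cfg$L, units = cfg$units,
         params = init_params(cfg$units, cfg$seed), config = cfg,
         trained = FALSE, history = numeric(0), provenance = NULL),
    class = "deep_filter"
  )
}

#' @export
print.deep_filter <- function(x, ...) {
  cat(sprintf(
    "<deep_filter> %s: 3 x %d LSTM units, L = %d, %s (%d epochs logged)\n",
    toupper(x$approach), x$units, x$L,
    if (x$trained) "trained" else "untrained", length(x$history)))
  invisible(x)
}

lr_for_epoch <- function(schedule, epoch) {
  hit <- schedule$from <= epoch & epoch <= schedule$to
  if (!any(hit)) schedule$rate[nrow(schedule)] else schedule$rate[which(hit)[1L]]
}

#' Train the deep filter
#'
#' Minimizes mean squared error between model outputs and the ground-truth
#' targets with Adam under the staged learning-rate schedule, recording the
#' mean training loss per epoch.  Deterministic given `cfg$seed` (single
#' precision, fixed operation order).  `epochs = 0` returns the model
#' unchanged with zero training steps.
#'
#' @param model A `deep_filter` from [build_model()].
#' @param ws A [build_training_set()] window set matching the model's
#'   approach and window length.
#' @param cfg A [train_config]; defaults to the one stored in the model.
#' @return The trained `deep_filter` with a `history` of per-epoch losses.
#' @export
train_deep_filter <- function(model, ws, cfg = model$config) {
  stopifnot(inherits(model, "deep_filter"), inherits(ws, "window_set"))
  if (ws$approach != model$approach)
    stop_config("window set built for ", ws$approach,
                " but model is ", model$approach)
  if (ws$L != model$L)
    stop_config("window length mismatch: set ", ws$L, ", model ", model$L)
  n_win <- nrow(ws$Y)
  params <- model$params
  if (cfg$epochs < 1L) {
    model$history <- numeric(0)
    return(model)
  }
  adam_m <- lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  step <- 0L
  mto <- model$approach == "mto"
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_for_epoch(cfg$lr_schedule, epoch)
      ord <- sample.int(n_win)
      batch_starts <- seq.int(1L, n_win, by = cfg$batch_size)
      losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- ord[batch_starts[bi]:min(batch_starts[bi] + cfg$batch_size - 1L,
                                        n_win)]
        Xb <- ws$Y[idx, , drop = FALSE]
        Gb <- if (mto) matrix(ws$G[idx], ncol = 1L)
              else ws$G[idx, , drop = FALSE]
        B <- length(idx)
        if (cfg$dropout > 0) {
          keep <- 1 - cfg$dropout
          m1 <- matrix(rbinom(B * model$units, 1L, keep), B, model$units)
          m2 <- matrix(rbinom(B * model$units, 1L, keep), B, model$units)
        } else {
          m1 <- m2 <- matrix(0, 0L, 0L)
        }
        res <- .lstm_batch_grad(params, Xb, Gb, model$approach,
                                m1, m2, cfg$dropout)
        losses[bi] <- res$loss
        step <- step + 1L
        bc1 <- 1 - beta1^step
        bc2 <- 1 - beta2^step
        for (k in seq_along(params)) {
          g <- res$grads[[k]]
          adam_m[[k]] <- beta1 * adam_m[[k]] + (1 - beta1) * g
          adam_v[[k]] <- beta2 * adam_v[[k]] + (1 - beta2) * g * g
          params[[k]] <- params[[k]] -
            lr * (adam_m[[k]] / bc1) / (sqrt(adam_v[[k]] / bc2) + eps)
        }
      }
      history[epoch] <- mean(losses)
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$history <- history
  model$config <- cfg
  model$provenance <- list(n_windows = n_win, L = ws$L, stride = ws$stride,
                           approach = ws$approach,
                           input_checksum = signif(sum(ws$Y), 12))
  model
}

model_window_fun <- function(model, approach) {
  if (is.function(model)) return(model)
  stopifnot(inherits(model, "deep_filter"))
  if (model$approach != approach)
    stop_config("model approach is ", model$approach, ", expected ", approach)
  function(wins) .lstm_predict(model$params, wins, approach)
}

#' Apply a many-to-one filter with input passthrough
#'
#' The first `L` output samples equal the input exactly (no window precedes
#' them); from position `L + 1` onward each sample is the model's forecast
#' from the preceding `L`-sample window.  Length is preserved.
#'
#' @param model A trained `deep_filter` with approach `"mto"`, or -- for
#'   window-level experimentation -- any function mapping a `W x L` window
#'   matrix to a length-`W` vector of forecasts (supply `L` then).
#' @param ts An [rppg_signal] longer than `L`.
#' @param L Window length; defaults to the model's.
#' @return The filtered [rppg_signal].
#' @export
apply_mto <- function(model, ts, L = NULL) {
  stopifnot(inherits(ts, "rppg_signal"))
  L <- L %||% model$L
  n <- length(ts$values)
  if (n <= L)
    stop_config("signal length ", n, " must exceed window length ", L)
  fun <- model_window_fun(model, "mto")
  wins <- build_windows(ts$values[-n], L, stride = 1L)  # windows ending <= n-1
  preds <- as.numeric(fun(wins))
  replace_values(ts, c(ts$values[seq_len(L)], preds))
}

#' Overlap-add reconstruction of windowed outputs
#'
#' Position `j` of the output accumulates element `j - s + 1` of every
#' window starting at `s <= j` that covers `j`.  With `normalize = TRUE`
#' the sum is divided by the number of contributing windows
#' (`min(j, L, n - j + 1, n - L + 1)`), so a window map that returns its
#' input reconstructs the input exactly.
#'
#' @param pred A `(n - L + 1) x L` matrix of filtered windows (stride 1).
#' @param n Output signal length.
#' @param normalize Divide by the per-position contribution count.
#' @return A length-`n` numeric vector.
#' @export
overlap_add <- function(pred, n, normalize = TRUE) {
  L <- ncol(pred)
  n_win <- n - L + 1L
  if (nrow(pred) != n_win)
    stop_config("expected ", n_win, " windows, got ", nrow(pred))
  out <- numeric(n)
  for (s in seq_len(n_win)) {
    idx <- s:(s + L - 1L)
    out[idx] <- out[idx] + pred[s, ]
  }
  if (normalize) {
    j <- seq_len(n)
    out <- out / pmin(j, L, n - j + 1L, n_win)
  }
  out
}

#' Apply a many-to-many filter with overlap-add reconstruction
#'
#' Every stride-1 window of the input is passed through the model; the
#' `L`-sample outputs are recombined by [overlap_add()].  Averaging over
#' the contributing windows (the default) preserves amplitude so quality
#' metrics are comparable before and after filtering;
#' `normalize_overlap = FALSE` gives the literal accumulated sum.
#'
#' @param model A trained `deep_filter` with approach `"mtm"`, or any
#'   function mapping a `W x L` window matrix to a `W x L` matrix of
#'   filtered windows (supply `L` then).
#' @param ts An [rppg_signal] of length >= `L`.
#' @param normalize_overlap Divide each position by its contribution count.
#' @param L Window length; defaults to the model's.
#' @return The filtered [rppg_signal] (length preserved).
#' @export
apply_mtm <- function(model, ts, normalize_overlap = TRUE, L = NULL) {
  stopifnot(inherits(ts, "rppg_signal"))
  L <- L %||% model$L
  n <- length(ts$values)
  if (n < L)
    stop_config("signal length ", n, " is below window length ", L)
  fun <- model_window_fun(model, "mtm")
  wins <- build_windows(ts$values, L, stride = 1L)
  pred <- fun(wins)
  if (!is.matrix(pred) || !all(dim(pred) == dim(wins)))
    stop_config("window map must return a matrix of the window shape")
  replace_values(ts, overlap_add(pred, n, normalize = normalize_overlap))
}

#' Save / load a deep-filter model
#'
#' The archive is self-describing: parameters, training configuration,
#' approach, window length and training provenance travel together.
#'
#' @param model A `deep_filter`.
#' @param path Archive path (RDS).
#' @return `save_deep_filter` returns `path` invisibly; `load_deep_filter`
#'   returns the model.
#' @export
save_deep_filter <- function(model, path) {
  stopifnot(inherits(model, "deep_filter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_deep_filter
#' @export
load_deep_filter <- function(path) {
  if (!file.exists(path)) stop_config("model archive not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "deep_filter"))
    stop_data("file is not a deep_filter archive: ", path)
  model
}
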