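# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Consistent condition classes so callers and the CLI can tell configuration
# mistakes from bad data.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("rppg_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("rppg_data_error", "error")))
}

# Centered moving average with shrinking windows at the edges; length
# preserving.  Used by the detrender and the reference smoother.
moving_average <- function(x, width) {
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
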