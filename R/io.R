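# Signal and corpus file I/O.
#
# CSV dialect: comma separator, "." decimal, optional "#"-prefixed metadata
# lines ("# key=value") before the data.  Data rows are either
# (time_s, value) pairs, or a single value column with the sampling rate
# supplied by a "# fs=<Hz>" line or the `fs_hint` argument.

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      meta[[key]] <- val
    }
  }
  meta
}

#' Read a signal from CSV
#'
#' Accepts either two-column `(time_s, value)` files, from which the sampling
#' rate is inferred as the reciprocal of the median inter-sample interval, or
#' value-only files whose rate comes from a `# fs=<Hz>` metadata line or the
#' `fs_hint` argument.
#'
#' @param path Path to a CSV file.
#' @param fs_hint Sampling rate in Hz, used when the file itself carries no
#'   rate information.
#' @param subject_id,role Metadata overrides; defaults come from `# key=value`
#'   lines in the file, falling back to the file name and `"rppg"`.
#'
#' @return An [rppg_signal].
#' @export
read_signal <- function(path, fs_hint = NULL, subject_id = NULL, role = NULL) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) == 0L) stop_data("no data rows in ", path)

  has_header <- grepl("[A-Za-z]", body[1L])
  if (has_header) body <- body[-1L]
  if (length(body) == 0L) stop_data("no data rows in ", path)

  fields <- strsplit(body, ",", fixed = TRUE)
  ncol <- length(fields[[1L]])
  num <- suppressWarnings(lapply(fields, as.numeric))
  values_idx <- if (ncol >= 2L) 2L else 1L
  values <- vapply(num, `[`, numeric(1), values_idx)
  if (anyNA(values)) {
    bad <- which(is.na(values))[1L]
    stop_data("non-finite or unparsable sample at data row ", bad,
              " of ", path)
  }

  fs <- NULL
  if (ncol >= 2L) {
    tcol <- vapply(num, `[`, numeric(1), 1L)
    if (anyNA(tcol)) stop_data("unparsable time value in ", path)
    dt <- median(diff(tcol))
    if (!is.finite(dt) || dt <= 0)
      stop_data("time column in ", path, " is not increasing")
    fs <- 1 / dt
  } else if (!is.null(meta$fs)) {
    fs <- as.numeric(meta$fs)
  } else if (!is.null(fs_hint)) {
    fs <- as.numeric(fs_hint)
  }
  if (is.null(fs) || !is.finite(fs))
    stop_config("no sampling rate: ", path,
                " has one column, no '# fs=' line, and no fs_hint")

  rppg_signal(
    values, fs,
    subject_id = subject_id %||% meta$subject_id %||%
      sub("\\.[^.]*$", "", basename(path)),
    role = role %||% meta$role %||% "rppg"
  )
}

#' Write a signal to CSV
#'
#' Emits `# fs=`, `# subject_id=` and `# role=` metadata lines followed by a
#' single `value` column with 15 significant digits, so that
#' [read_signal()] round-trips values to better than 1e-9 relative error and
#' the sampling rate exactly.
#'
#' @param ts An [rppg_signal].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal <- function(ts, path) {
  stopifnot(inherits(ts, "rppg_signal"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_config("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.15g", ts$fs),
    sprintf("# subject_id=%s", ts$subject_id),
    sprintf("# role=%s", ts$role),
    "value",
    sprintf("%.15g", ts$values)
  ), con)
  invisible(path)
}

#' Read a corpus manifest from CSV
#' @param path Manifest CSV path (columns `subject_id`, `rppg_path`,
#'   `gt_path`, `duration_s`, `snr_db`).
#' @return A [corpus_manifest].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  corpus_manifest(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character")))
}

#' Write a corpus manifest to CSV
#' @param manifest A [corpus_manifest].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Write a corpus (pairs + manifest) to a directory
#'
#' Each pair becomes `<subject_id>_rppg.csv` and `<subject_id>_gt.csv`;
#' the manifest, with paths filled in, is written as `manifest.csv`.
#'
#' @param corpus An `rppg_corpus` as returned by [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest with resolved paths.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "rppg_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- as.data.frame(corpus$manifest)
  for (i in seq_along(corpus$pairs)) {
    p <- corpus$pairs[[i]]
    rp <- file.path(dir, paste0(p$rppg$subject_id, "_rppg.csv"))
    gp <- file.path(dir, paste0(p$gt$subject_id, "_gt.csv"))
    write_signal(p$rppg, rp)
    write_signal(p$gt, gp)
    man$rppg_path[i] <- rp
    man$gt_path[i] <- gp
  }
  man <- corpus_manifest(man)
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Read a corpus from a directory written by [write_corpus()]
#' @param dir Directory containing `manifest.csv` and the signal files.
#' @return An `rppg_corpus`: list with `manifest` and `pairs`.
#' @export
read_corpus <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  pairs <- lapply(seq_len(nrow(man)), function(i) {
    r <- read_signal(man$rppg_path[i])
    g <- read_signal(man$gt_path[i])
    signal_pair(r, g)
  })
  structure(list(manifest = man, pairs = pairs), class = "rppg_corpus")
}

#' @export
print.rppg_corpus <- function(x, ...) {
  print(x$manifest)
  invisible(x)
}
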