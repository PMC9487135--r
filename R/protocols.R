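# Experiment protocols: SNR quality labels, subject-independent splits,
# stratified subsampling, quality grouping, and the four experiment kinds
# (intra-corpus CV + final evaluation, cross-corpus, amount-of-training-data,
# SNR dependence).

#' Quality labels from SNR values
#'
#' The observed SNR range is divided into four sub-ranges of width
#' `h = (max - min) / 4`; label 0 covers `[min, min + h)`, 1 covers
#' `[min + h, min + 2h)`, 2 covers `[min + 2h, max - h)` and 3 covers
#' `[max - h, max]`.  Every finite value receives exactly one label; the
#' minimum always gets 0 and the maximum always gets 3.
#'
#' @param snr_values Numeric vector of SNR values in dB (>= 2 distinct).
#' @return Integer vector of labels in `0:3`.
#' @export
snr_labels <- function(snr_values) {
  if (!all(is.finite(snr_values))) stop_data("SNR values must be finite")
  lo <- min(snr_values)
  hi <- max(snr_values)
  if (hi <= lo) stop_data("all SNR values equal: label width h = 0")
  h <- (hi - lo) / 4
  ifelse(snr_values < lo + h, 0L,
         ifelse(snr_values < lo + 2 * h, 1L,
                ifelse(snr_values < hi - h, 2L, 3L)))
}

#' Subject-independent k-fold split plan
#'
#' Shuffles subjects under `seed`, holds out 20% for a final evaluation and
#' partitions the remaining 80% into `k` subject-disjoint folds of
#' near-equal size (within one subject).
#'
#' @param manifest A [corpus_manifest].
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param test_fraction Held-out fraction for the final evaluation.
#' @return An object of class `split_plan`: list with `folds` (list of `k`
#'   subject-id vectors), `test_subjects`, `k`, `seed`.
#' @export
subject_kfold <- function(manifest, k = 5L, seed = 1L, test_fraction = 0.2) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  subjects <- unique(manifest$subject_id)
  n <- length(subjects)
  n_test <- max(1L, round(test_fraction * n))
  if (n - n_test < k)
    stop_config("need at least ", k + n_test, " subjects for ", k,
                " folds plus a held-out set; have ", n)
  with_seed(seed, {
    shuffled <- sample(subjects)
    test_subjects <- shuffled[seq_len(n_test)]
    pool <- shuffled[-seq_len(n_test)]
    folds <- split(pool, rep_len(seq_len(k), length(pool)))
    names(folds) <- paste0("fold", seq_len(k))
    structure(list(folds = folds, test_subjects = test_subjects,
                   k = k, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d folds (%s subjects) + %d held-out\n", x$k,
              paste(lengths(x$folds), collapse = "/"),
              length(x$test_subjects)))
  invisible(x)
}

#' Stratified fraction of a corpus
#'
#' Signals are binned into SNR quartiles and a seeded sample of
#' approximately `fraction` is drawn from each bin (largest-remainder
#' allocation, at least one signal overall), so the sub-corpus preserves
#' the parent's SNR balance.
#'
#' @param manifest A [corpus_manifest].
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return A [corpus_manifest] with `round(fraction * n)` rows (>= 1).
#' @export
stratified_fraction <- function(manifest, fraction, seed = 1L) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  if (fraction <= 0 || fraction > 1)
    stop_config("fraction must lie in (0, 1]")
  n <- nrow(manifest)
  target <- max(1L, round(fraction * n))
  if (fraction == 1) return(manifest)
  qs <- quantile(manifest$snr_db, probs = c(0.25, 0.5, 0.75), type = 7)
  bin <- findInterval(manifest$snr_db, qs, rightmost.closed = FALSE) + 1L
  with_seed(seed, {
    bins <- split(seq_len(n), bin)
    raw <- target * lengths(bins) / n
    take <- floor(raw)
    rem <- target - sum(take)
    if (rem > 0) {
      extra <- order(raw - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    take <- pmin(take, lengths(bins))
    picked <- unlist(mapply(function(idx, m) {
      if (m >= 1L) sample(idx, m) else integer(0)
    }, bins, take, SIMPLIFY = FALSE), use.names = FALSE)
    if (length(picked) == 0L) stop_config("empty stratified sample")
    corpus_manifest(manifest[sort(picked), , drop = FALSE])
  })
}

#' Contiguous SNR quality groups
#'
#' Subjects are ranked by mean SNR (best first) and cut into `n_groups`
#' contiguous groups of near-equal signal counts; group 1 holds the
#' highest-SNR signals, the last group the lowest.
#'
#' @param manifest A [corpus_manifest].
#' @param n_groups Number of groups.
#' @return List of [corpus_manifest] objects, best to worst, which
#'   partition the input.
#' @export
quality_groups <- function(manifest, n_groups = 5L) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  n <- nrow(manifest)
  if (n < n_groups) stop_config("fewer signals (", n, ") than groups")
  subj_snr <- tapply(manifest$snr_db, manifest$subject_id, mean)
  ord <- order(-subj_snr[manifest$subject_id],
               manifest$subject_id)  # best first; ids break ties
  bounds <- round(seq(0, n, length.out = n_groups + 1L))
  lapply(seq_len(n_groups), function(g) {
    rows <- ord[(bounds[g] + 1L):bounds[g + 1L]]
    corpus_manifest(manifest[rows, , drop = FALSE])
  })
}

# ---- experiment engine ------------------------------------------------------

#' Filter specification for experiments
#'
#' @param type One of `"bandpass"`, `"wavelet"`, `"savgol"`, `"identity"`,
#'   `"mto"`, `"mtm"`.
#' @param cfg For the learned types, a [train_config].
#' @param ... Extra arguments stored for the classical filters.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(type = c("bandpass", "wavelet", "savgol", "identity",
                                 "mto", "mtm"),
                        cfg = NULL, ...) {
  type <- match.arg(type)
  learned <- type %in% c("mto", "mtm")
  if (learned && is.null(cfg)) cfg <- train_config()
  structure(list(type = type, cfg = cfg, args = list(...), learned = learned),
            class = "filter_spec")
}

assert_disjoint <- function(train_ids, test_ids, cell) {
  overlap <- intersect(unique(train_ids), unique(test_ids))
  if (length(overlap) > 0L)
    stop("internal consistency error: train/test subject overlap in cell '",
         cell, "': ", paste(head(overlap, 5L), collapse = ", "))
  invisible(TRUE)
}

pairs_for_subjects <- function(corpus, subjects) {
  keep <- corpus$manifest$subject_id %in% subjects
  corpus$pairs[keep]
}

# Train (if needed) on the train pairs, filter the test pairs, evaluate.
run_cell <- function(spec, train_pairs, test_pairs, cell_name) {
  train_ids <- vapply(train_pairs, function(p) p$rppg$subject_id, character(1))
  test_ids <- vapply(test_pairs, function(p) p$rppg$subject_id, character(1))
  assert_disjoint(train_ids, test_ids, cell_name)
  filt <- if (spec$learned) {
    ws <- build_training_set(train_pairs, spec$type, spec$cfg)
    model <- build_model(spec$type, spec$cfg)
    model <- train_deep_filter(model, ws)
    if (spec$type == "mto") function(ts) apply_mto(model, ts)
    else function(ts) apply_mtm(model, ts)
  } else {
    switch(spec$type,
      bandpass = function(ts) do.call(bandpass, c(list(ts), spec$args)),
      wavelet = function(ts) do.call(wavelet_denoise, c(list(ts), spec$args)),
      savgol = function(ts) do.call(savgol, c(list(ts), spec$args)),
      identity = function(ts) ts)
  }
  reports <- lapply(test_pairs, function(p) evaluate_pair(p, filt(p$rppg)))
  list(summary = aggregate_reports(reports), reports = reports,
       train_ids = unique(train_ids), test_ids = unique(test_ids))
}

summary_row <- function(kind, filter_name, cell, train_tag, test_tag, res) {
  s <- res$summary
  g <- function(m, col) s[s$metric == m, col]
  data.frame(
    kind = kind, filter = filter_name, cell = cell,
    train = train_tag, test = test_tag,
    n_train_subjects = length(res$train_ids),
    n_test_signals = s$n[1],
    mae = g("mae", "mean"), mae_lo = g("mae", "ci_lo"),
    mae_hi = g("mae", "ci_hi"),
    r = g("r", "mean"),
    snr = g("snr", "mean"), snr_lo = g("snr", "ci_lo"),
    snr_hi = g("snr", "ci_hi"),
    tmc = g("tmc", "mean"), tmc_lo = g("tmc", "ci_lo"),
    tmc_hi = g("tmc", "ci_hi"),
    stringsAsFactors = FALSE
  )
}

preprocess_corpus <- function(corpus, ...) {
  corpus$pairs <- lapply(corpus$pairs, preprocess_pair, ...)
  corpus
}

#' Run an evaluation protocol
#'
#' Four experiment kinds, each structurally subject-disjoint and
#' seed-reproducible:
#'
#' * `"intra"`: subject-independent k-fold cross-validation inside an 80%
#'   training pool plus a final evaluation on the held-out 20%, per filter.
#' * `"cross"`: every ordered pair of corpora, training on one and testing
#'   on the other.
#' * `"amount"`: training on stratified fractions of the 80% pool (default
#'   100/50/25/10/5/1%), always testing on the held-out 20%.
#' * `"snr_dependence"`: the 80% pool is cut into SNR quality groups; each
#'   group trains a model tested on the held-out set, and a model trained
#'   on the held-out set is tested on each group.
#'
#' All pairs are preprocessed (see [preprocess_pair()]) before any window
#' is built; classical filters are applied to the same preprocessed inputs.
#'
#' @param kind Experiment kind.
#' @param corpora A named list of `rppg_corpus` objects (one for `"intra"`,
#'   `"amount"` and `"snr_dependence"`; two or more for `"cross"`).
#' @param filters Named list of [filter_spec] objects.
#' @param seed Integer seed governing every split.
#' @param k Folds for `"intra"`.
#' @param fractions Training fractions for `"amount"`.
#' @param n_groups Quality groups for `"snr_dependence"`.
#' @return An `experiment_report`: data frame with one row per
#'   (filter, cell), plus an `audit` attribute recording every split.
#' @export
run_experiment <- function(kind = c("intra", "cross", "amount",
                                    "snr_dependence"),
                           corpora, filters, seed = 1L, k = 5L,
                           fractions = c(1, 0.5, 0.25, 0.1, 0.05, 0.01),
                           n_groups = 5L) {
  kind <- match.arg(kind)
  stopifnot(is.list(corpora), length(corpora) >= 1L,
            all(vapply(corpora, inherits, logical(1), "rppg_corpus")))
  if (is.null(names(corpora)))
    names(corpora) <- paste0("corpus", seq_along(corpora))
  stopifnot(all(vapply(filters, inherits, logical(1), "filter_spec")))
  if (is.null(names(filters)))
    names(filters) <- vapply(filters, `[[`, character(1), "type")
  corpora <- lapply(corpora, preprocess_corpus)
  rows <- list()
  audit <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  if (kind == "cross") {
    if (length(corpora) < 2L) stop_config("cross needs >= 2 corpora")
    for (a in names(corpora)) for (b in names(corpora)) {
      if (a == b) next
      for (fn in names(filters)) {
        res <- run_cell(filters[[fn]], corpora[[a]]$pairs,
                        corpora[[b]]$pairs, paste(a, "->", b))
        add(summary_row(kind, fn, paste0(a, "->", b), a, b, res))
        audit[[paste(fn, a, b, sep = "|")]] <-
          list(train = res$train_ids, test = res$test_ids)
      }
    }
  } else {
    corpus <- corpora[[1L]]
    cname <- names(corpora)[1L]
    # only the intra protocol needs the k-fold structure; the others just
    # use the 80/20 subject split
    plan <- subject_kfold(corpus$manifest,
                          k = if (kind == "intra") k else 1L, seed = seed)
    test_pairs <- pairs_for_subjects(corpus, plan$test_subjects)
    pool_subjects <- unlist(plan$folds, use.names = FALSE)
    pool_manifest <- corpus_manifest(
      corpus$manifest[corpus$manifest$subject_id %in% pool_subjects, ,
                      drop = FALSE])
    audit$plan <- plan

    if (kind == "intra") {
      for (fn in names(filters)) {
        for (f in seq_len(k)) {
          tr <- pairs_for_subjects(corpus,
                                   setdiff(pool_subjects, plan$folds[[f]]))
          te <- pairs_for_subjects(corpus, plan$folds[[f]])
          res <- run_cell(filters[[fn]], tr, te, paste0(fn, "/fold", f))
          add(summary_row(kind, fn, paste0("fold", f), cname, cname, res))
        }
        res <- run_cell(filters[[fn]],
                        pairs_for_subjects(corpus, pool_subjects),
                        test_pairs, paste0(fn, "/final"))
        add(summary_row(kind, fn, "final", cname, cname, res))
      }
    } else if (kind == "amount") {
      for (fr in fractions) {
        sub_man <- stratified_fraction(pool_manifest, fr, seed = seed)
        audit[[sprintf("fraction_%g", fr)]] <- sub_man$subject_id
        tr <- pairs_for_subjects(corpus, sub_man$subject_id)
        for (fn in names(filters)) {
          res <- run_cell(filters[[fn]], tr, test_pairs,
                          sprintf("%s/frac%g", fn, fr))
          add(summary_row(kind, fn, sprintf("frac%g", fr),
                          sprintf("%s[%g%%]", cname, 100 * fr), cname, res))
        }
      }
    } else {  # snr_dependence
      groups <- quality_groups(pool_manifest, n_groups = n_groups)
      audit$groups <- lapply(groups, function(g) g$subject_id)
      for (g in seq_along(groups)) {
        tr <- pairs_for_subjects(corpus, groups[[g]]$subject_id)
        for (fn in names(filters)) {
          res <- run_cell(filters[[fn]], tr, test_pairs,
                          sprintf("%s/group%d->held-out", fn, g - 1L))
          add(summary_row(kind, fn, sprintf("Q%d->held-out", g - 1L),
                          sprintf("Q%d", g - 1L), "held-out", res))
        }
      }
      tr <- test_pairs  # reverse direction: held-out trains, groups test
      for (g in seq_along(groups)) {
        te <- pairs_for_subjects(corpus, groups[[g]]$subject_id)
        for (fn in names(filters)) {
          res <- run_cell(filters[[fn]], tr, te,
                          sprintf("%s/held-out->group%d", fn, g - 1L))
          add(summary_row(kind, fn, sprintf("held-out->Q%d", g - 1L),
                          "held-out", sprintf("Q%d", g - 1L), res))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "audit") <- audit
  attr(out, "seed") <- seed
  class(out) <- c("experiment_report", "data.frame")
  out
}

#' Write an experiment report to a directory
#'
#' One CSV per experiment cell-set plus a JSON summary with the seed and
#' split audit, so any run can be reproduced from its emitted parameters.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_experiment <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(report), file.path(dir, "cells.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(seed = attr(report, "seed"),
         audit = attr(report, "audit")),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, force = TRUE, pretty = TRUE
  )
  invisible(dir)
}
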