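# Window construction, model shapes, training mechanics, and the two
# inference modes with their passthrough / overlap-add contracts.

test_that("build_windows counts and placements follow the stride formula", {
  expect_identical(nrow(build_windows(1:6, 3)), 4L)
  w <- build_windows(1:5, 5)
  expect_identical(dim(w), c(1L, 5L))
  expect_equal(w[1, ], 1:5)

  w2 <- build_windows(1:10, 3, stride = 4)
  expect_identical(nrow(w2), 2L)
  expect_equal(w2[1, ], 1:3)
  expect_equal(w2[2, ], 5:7)

  expect_error(build_windows(1:4, 5), class = "rppg_config_error")

  set.seed(15)
  for (i in 1:30) {
    T_ <- sample(5:200, 1)
    L <- sample(2:min(T_, 30), 1)
    stride <- sample(1:10, 1)
    n <- nrow(build_windows(seq_len(T_), L, stride))
    expect_identical(n, as.integer(floor((T_ - L) / stride) + 1))
  }
})

make_seq_pairs <- function(T_) {
  # rppg counts up, gt counts down: targets are easy to verify positionally
  lapply(1:2, function(i) {
    signal_pair(
      rppg_signal(seq_len(T_) + 1000 * i, 25, subject_id = paste0("s", i)),
      rppg_signal(-(seq_len(T_) + 1000 * i), 25,
                  subject_id = paste0("s", i), role = "ground_truth")
    )
  })
}

test_that("training sets pair windows with the right targets", {
  cfg <- train_config(L = 125L, stride = 1L, units = 4L)
  pairs <- make_seq_pairs(200L)

  mtm <- build_training_set(pairs, "mtm", cfg)
  expect_identical(nrow(mtm$Y), 2L * (200L - 125L + 1L))
  expect_identical(ncol(mtm$G), 125L)
  expect_equal(mtm$G[1, ], pairs[[1]]$gt$values[1:125])
  expect_equal(mtm$Y[1, ], pairs[[1]]$rppg$values[1:125])

  mto <- build_training_set(pairs, "mto", cfg)
  expect_identical(nrow(mto$Y), 2L * (200L - 126L + 1L))
  expect_identical(length(mto$G), nrow(mto$Y))
  # the target is the ground-truth sample one past the window
  expect_equal(mto$G[1], pairs[[1]]$gt$values[126])
  expect_equal(mto$Y[5, ], pairs[[1]]$rppg$values[5:129])
  expect_equal(mto$G[5], pairs[[1]]$gt$values[130])

  expect_error(build_training_set(list(), "mtm", cfg),
               class = "rppg_config_error")
})

test_that("model outputs have the contracted shapes and seeded init", {
  cfg <- train_config(units = 6L, L = 30L, seed = 44L)
  mto <- build_model("mto", cfg)
  mtm <- build_model("mtm", cfg)
  X <- matrix(rnorm(5 * 30), 5, 30)
  expect_identical(dim(rppgfilter:::.lstm_predict(mto$params, X, "mto")),
                   c(5L, 1L))
  expect_identical(dim(rppgfilter:::.lstm_predict(mtm$params, X, "mtm")),
                   c(5L, 30L))

  again <- build_model("mto", cfg)
  expect_identical(mto$params, again$params)
  other <- build_model("mto", train_config(units = 6L, L = 30L, seed = 45L))
  expect_false(identical(mto$params, other$params))
})

test_that("many-to-one filtering passes the first L samples through", {
  cfg <- train_config(units = 5L, L = 20L, seed = 2L)
  m <- build_model("mto", cfg)
  s <- sine_signal(1.2, 25, 10)
  out <- apply_mto(m, s)
  expect_identical(length(out$values), length(s$values))
  expect_identical(out$values[1:20], s$values[1:20])

  s126 <- rppg_signal(rnorm(21), 25)
  o <- apply_mto(m, s126)
  expect_identical(o$values[1:20], s126$values[1:20])
  expect_false(o$values[21] == s126$values[21])

  expect_error(apply_mto(m, rppg_signal(rnorm(20), 25)),
               class = "rppg_config_error")
})

test_that("overlap-add matches per-position counting rules", {
  # a map returning all-ones windows turns unnormalized overlap-add into a
  # per-position window count
  ones_map <- function(w) matrix(1, nrow(w), ncol(w))
  n <- 40L; L <- 7L
  s <- rppg_signal(rnorm(n), 25)
  counts <- apply_mtm(ones_map, s, normalize_overlap = FALSE, L = L)$values
  j <- seq_len(n)
  expect_equal(counts, pmin(j, L, n - j + 1L, n - L + 1L))
  interior <- j[j >= L & j <= n - L + 1L]
  expect_true(all(counts[interior] == L))

  # identity map with normalization reconstructs the input
  id_map <- function(w) w
  back <- apply_mtm(id_map, s, L = L)$values
  expect_equal(back, s$values, tolerance = 1e-14)
})

test_that("training reduces the loss, is seed-reproducible, and epochs = 0
           is a no-op", {
  pairs <- make_pairs(4, seed = 61, duration_s = 15)
  cfg <- train_config(units = 8L, L = 25L, epochs = 3L, stride = 5L,
                      seed = 10L)
  ws <- build_training_set(pairs, "mtm", cfg)
  m0 <- build_model("mtm", cfg)

  m1 <- train_deep_filter(m0, ws)
  expect_length(m1$history, 3L)
  expect_lte(m1$history[3], m1$history[1])
  expect_true(m1$trained)

  m2 <- train_deep_filter(m0, ws)
  expect_identical(m1$params, m2$params)

  noop <- train_deep_filter(m0, ws, train_config(
    units = 8L, L = 25L, epochs = 0L, stride = 5L, seed = 10L))
  expect_identical(noop$params, m0$params)
  expect_length(noop$history, 0L)

  bad <- build_training_set(pairs, "mto", cfg)
  expect_error(train_deep_filter(m0, bad), class = "rppg_config_error")
})

test_that("model archives round-trip", {
  cfg <- train_config(units = 4L, L = 10L, seed = 3L)
  m <- build_model("mtm", cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_deep_filter(m, path)
  back <- load_deep_filter(path)
  expect_identical(back$params, m$params)
  expect_identical(back$approach, "mtm")
  expect_error(load_deep_filter(withr::local_tempfile()),
               class = "rppg_config_error")
})
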