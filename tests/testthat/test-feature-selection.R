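test_that("binarize_mask thresholds at 0.5 and round-trips binary input", {
  pos <- c(0.9, 0.8, 0.2, 0.6, 0.1, 0.4, 0.7, 0.9, 0.3)
  mask <- binarize_mask(pos)
  expect_identical(mask_string(mask), "110100110")
  expect_identical(which(mask == 1L), c(1L, 2L, 4L, 7L, 8L))
  expect_identical(binarize_mask(rep(0, 4)), rep(0L, 4))
  expect_identical(binarize_mask(c(0.5, 0.49999)), c(1L, 0L))
  # idempotent on binary input; out-of-range values handled by comparison
  m <- c(1L, 0L, 1L)
  expect_identical(binarize_mask(as.numeric(m)), m)
  expect_identical(binarize_mask(c(-3, 7)), c(0L, 1L))
  expect_error(binarize_mask(c(0.2, NaN)), "finite")
})

test_that("repair_mask flips exactly one random bit on empty masks only", {
  expect_identical(repair_mask(c(1L, 0L, 1L)), c(1L, 0L, 1L))
  set.seed(4)
  for (i in 1:50) {
    r <- repair_mask(rep(0L, 5))
    expect_identical(sum(r), 1L)
  }
  set.seed(99); a <- repair_mask(rep(0L, 8))
  set.seed(99); b <- repair_mask(rep(0L, 8))
  expect_identical(a, b)
})

test_that("decode_position is deterministic and never empty", {
  expect_identical(decode_position(c(0.9, 0.2, 0.6)), c(1L, 0L, 1L))
  # empty decode falls back to the argmax coordinate, ties to lowest index
  expect_identical(decode_position(c(0.1, 0.4, 0.2)), c(0L, 1L, 0L))
  expect_identical(decode_position(c(0.3, 0.3)), c(1L, 0L))
  expect_gte(sum(decode_position(runif(20, 0, 0.49))), 1L)
})

test_that("knn error matches the brute-force oracle on tiny fixtures", {
  for (seed in 1:4) {
    ds <- make_tiny_dataset(n = 14, D = 5, n_signal = 2, delta = 2,
                            seed = seed)
    set.seed(seed)
    ds <- split_dataset(ds)
    for (mask in list(rep(1L, 5), c(1L, 1L, 0L, 0L, 0L),
                      c(0L, 0L, 1L, 1L, 1L))) {
      for (k in c(1, 3, 5)) {
        expect_equal(knn_error_rate(ds, mask, k),
                     oracle_knn_error(ds, mask, k),
                     info = sprintf("seed %d k %d", seed, k))
      }
    }
  }
})

test_that("unanimous duplicated neighborhoods give zero error", {
  # every evaluation point duplicated k times in training with one label
  X <- rbind(matrix(rep(c(0, 0), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(5, 5), 3), 3, 2, byrow = TRUE),
             c(0, 0), c(5, 5))
  y <- c(1, 1, 1, 2, 2, 2, 1, 2)
  ds <- labeled_dataset(X, y, train = 1:6, test = 7:8)
  expect_identical(knn_error_rate(ds, c(1L, 1L), k = 3), 0)
})

test_that("label-independent features give chance-level error", {
  # 2 balanced classes, labels independent of features -> error ~ 0.5
  set.seed(123)
  errs <- replicate(30, {
    X <- matrix(rnorm(200 * 4), 200, 4)
    y <- rep(1:2, 100)
    ds <- labeled_dataset(X, y)
    ds <- split_dataset(ds)
    knn_error_rate(ds, rep(1L, 4), 5)
  })
  # Monte-Carlo reference: mean within a generous CI of 0.5
  expect_gt(mean(errs), 0.4)
  expect_lt(mean(errs), 0.6)
})

test_that("knn error validates its preconditions", {
  ds <- make_tiny_dataset(n = 10, D = 4, seed = 2)
  set.seed(2); ds <- split_dataset(ds)
  expect_error(knn_error_rate(ds, rep(0L, 4)), "at least one")
  expect_error(knn_error_rate(ds, rep(1L, 4), k = 100), "training")
  ds_nosplit <- make_tiny_dataset(n = 10, D = 4, seed = 2)
  expect_error(knn_error_rate(ds_nosplit, rep(1L, 4)), "partition")
})

test_that("fitness combines error and subset fraction with alpha weights", {
  ds <- make_tiny_dataset(n = 20, D = 9, n_signal = 3, delta = 6, seed = 5)
  set.seed(5); ds <- split_dataset(ds)
  cfg <- fitness_config(alpha = 0.99, k = 3)
  # strong signal: the 3 signal features classify perfectly
  mask_sig <- c(rep(1L, 3), rep(0L, 6))
  expect_equal(knn_error_rate(ds, mask_sig, 3), 0)
  f <- evaluate_fitness(ds, as.numeric(mask_sig), cfg)
  expect_equal(f, 0.01 * 3 / 9)
  # worked arithmetic: error 0.2 with 5 of 9 features
  expect_equal(0.99 * 0.2 + 0.01 * 5 / 9, 0.2035556, tolerance = 1e-6)
  # bounds and monotonicity: adding a feature at fixed error adds
  # exactly beta / |ALL| to the size term
  full <- evaluate_fitness(ds, rep(1, 9), cfg)
  expect_gte(full, 0); expect_lte(full, 1)
  err_full <- knn_error_rate(ds, rep(1L, 9), 3)
  expect_equal(full, 0.99 * err_full + 0.01)
})

test_that("stratified split honors fraction, classes, and determinism", {
  ds <- make_tiny_dataset(n = 10, D = 3, seed = 6)
  set.seed(1); sp <- split_dataset(ds, 0.7)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), 1:10)
  # both classes in training
  expect_identical(sort(unique(sp$labels[sp$train])), c(1L, 2L))
  set.seed(1); sp2 <- split_dataset(ds, 0.7)
  expect_identical(sp$train, sp2$train)
  expect_error(split_dataset(ds, 1), "train_fraction")
  # single-sample class forced into training with a warning
  X <- matrix(rnorm(12), 6, 2)
  dsing <- labeled_dataset(X, c(1, 1, 1, 1, 1, 2))
  expect_warning(spw <- split_dataset(dsing, 0.5), "single sample")
  expect_true(6 %in% spw$train)
})

test_that("select_features returns a coherent result record", {
  ds <- make_tiny_dataset(n = 20, D = 6, n_signal = 2, delta = 5, seed = 3)
  res <- select_features(ds, method = "soschoa", n_pop = 6, t_max = 15,
                         seed = 3)
  expect_s3_class(res, "fs_result")
  expect_identical(res$selected, which(res$mask == 1L))
  expect_identical(nchar(res$mask_string), 6L)
  expect_gte(res$n_selected, 1L)
  expect_equal(res$accuracy, 1 - res$error_rate)
  expect_length(res$run$convergence, 16)
  # deterministic under seed
  res2 <- select_features(ds, method = "soschoa", n_pop = 6, t_max = 15,
                          seed = 3)
  expect_identical(res$mask, res2$mask)
  expect_identical(res$fitness, res2$fitness)
})
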