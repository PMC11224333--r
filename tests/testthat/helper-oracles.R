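# Fixture builders and independent oracles used across the suite.

# Tiny deterministic 2-class dataset: class means +/- delta on the first
# `n_signal` features, standard-normal elsewhere.
make_tiny_dataset <- function(n = 20, D = 6, n_signal = 2, delta = 3,
                              seed = 1) {
  set.seed(seed)
  y <- rep(1:2, length.out = n)
  X <- matrix(rnorm(n * D), n, D)
  X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] +
    delta * (y == 2)
  soschoa::labeled_dataset(X, y)
}

# Brute-force KNN oracle: explicit loops, full pairwise Euclidean
# distances, distance ties -> lower training index, vote ties -> smallest
# class label. Deliberately independent of the package's vectorized path.
oracle_knn_error <- function(dataset, mask, k) {
  sel <- which(mask == 1L)
  tr_i <- dataset$train; te_i <- dataset$test
  wrong <- 0L
  for (j in te_i) {
    d <- numeric(length(tr_i))
    for (a in seq_along(tr_i)) {
      diff <- dataset$features[tr_i[a], sel] - dataset$features[j, sel]
      d[a] <- sqrt(sum(diff^2))
    }
    ord <- seq_along(tr_i)[order(round(d, 10), seq_along(tr_i))]
    nb_labels <- dataset$labels[tr_i[ord[seq_len(k)]]]
    counts <- table(nb_labels)
    winners <- as.integer(names(counts)[counts == max(counts)])
    pred <- min(winners)
    if (pred != dataset$labels[j]) wrong <- wrong + 1L
  }
  wrong / length(te_i)
}

# Exhaustive wrapper-fitness oracle over all 2^D - 1 non-empty masks.
oracle_enumerate_fitness <- function(dataset, cfg = soschoa::fitness_config()) {
  D <- ncol(dataset$features)
  masks <- as.matrix(expand.grid(rep(list(0:1), D)))[-1, , drop = FALSE]
  fits <- apply(masks, 1, function(m) {
    err <- soschoa::knn_error_rate(dataset, as.integer(m), cfg$k)
    cfg$alpha * err + cfg$beta * sum(m) / D
  })
  list(masks = masks, fitness = fits, optimum = min(fits))
}

quadratic_objective <- function(x) sum(x^2)
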