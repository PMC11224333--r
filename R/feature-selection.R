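#' Construct a labeled dataset
#'
#' Container for a samples x features numeric matrix with class labels and
#' an optional train/test partition. Labels are re-encoded to consecutive
#' integers 1..K internally; the original values are kept in
#' `label_levels`.
#'
#' @param features Numeric matrix (samples as rows).
#' @param labels Vector of class labels, one per row.
#' @param train,test Optional disjoint, exhaustive row-index partition.
#' @return An object of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(features, labels, train = NULL, test = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(features) != length(labels)) {
    stop(sprintf("label length (%d) does not match sample count (%d)",
                 length(labels), nrow(features)), call. = FALSE)
  }
  levels <- sort(unique(labels))
  y <- match(labels, levels)
  if (!is.null(train) || !is.null(test)) {
    idx <- sort(c(train, test))
    if (anyDuplicated(c(train, test)) ||
        !identical(idx, seq_len(nrow(features)))) {
      stop("partition must be disjoint and cover all samples",
           call. = FALSE)
    }
    if (length(unique(y[train])) < length(levels)) {
      stop("every class must appear in the training partition",
           call. = FALSE)
    }
  }
  structure(list(features = features, labels = y, label_levels = levels,
                 train = train, test = test),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), length(x$label_levels)))
  if (!is.null(x$train)) {
    cat(sprintf("  partition: %d train / %d test\n",
                length(x$train), length(x$test)))
  }
  invisible(x)
}

#' Decode a continuous position into a binary feature mask
#'
#' Coordinate j selects feature j iff `position[j] >= 0.5`. Values outside
#' `[0, 1]` are handled by the comparison itself; exactly 0.5 selects.
#'
#' @param position Numeric vector of finite values.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' binarize_mask(c(0.9, 0.8, 0.2, 0.6, 0.1, 0.4, 0.7, 0.9, 0.3))
#' @export
binarize_mask <- function(position) {
  if (any(!is.finite(position))) {
    stop("`position` must be finite", call. = FALSE)
  }
  as.integer(position >= 0.5)
}

#' Repair an empty feature mask
#'
#' A wrapper fitness is undefined on the empty subset; if no bit is set,
#' exactly one uniformly random bit is switched on. Non-empty masks pass
#' through unchanged. Consumes the R RNG.
#'
#' @param mask Integer 0/1 vector.
#' @return A mask with at least one bit set.
#' @export
repair_mask <- function(mask) {
  stopifnot(all(mask %in% c(0L, 1L)))
  if (sum(mask) == 0L) {
    mask[sample.int(length(mask), 1L)] <- 1L
  }
  mask
}

#' Render a mask as a Location string
#'
#' @param mask Integer 0/1 vector.
#' @return Single string such as `"110100110"`.
#' @export
mask_string <- function(mask) paste(as.integer(mask), collapse = "")

# Predict labels of `test_x` by k-nearest neighbours on `train_x`
# (Euclidean distance; distance ties -> lower training index, vote ties ->
# smallest class label). Internal: inputs already restricted to the
# selected features.
knn_predict <- function(train_x, train_y, test_x, k) {
  ntr <- nrow(train_x)
  if (k > ntr) stop("`k` exceeds the training-set size", call. = FALSE)
  # squared Euclidean distances, train x test
  d2 <- matrix(rowSums(train_x^2), ntr, nrow(test_x)) -
    2 * tcrossprod(train_x, test_x)
  d2 <- round(d2, 12)  # stabilise exact-tie detection against FP noise
  pred <- integer(nrow(test_x))
  for (j in seq_len(nrow(test_x))) {
    nb <- order(d2[, j], seq_len(ntr))[seq_len(k)]
    votes <- tabulate(train_y[nb])
    pred[j] <- which.max(votes)  # first max = smallest class label
  }
  pred
}

#' Held-out KNN misclassification rate of a feature subset
#'
#' Trains a k-nearest-neighbour classifier (Euclidean distance) on the
#' training partition restricted to the selected features and scores it on
#' the held-out partition. Distance ties are broken by lower training
#' index, vote ties by smallest class label.
#'
#' @param dataset A partitioned [labeled_dataset()].
#' @param mask Non-empty 0/1 feature mask of length D.
#' @param k Neighbour count; protocol default 5.
#' @return Misclassification rate in `[0, 1]`.
#' @export
knn_error_rate <- function(dataset, mask, k = 5) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(dataset$train)) {
    stop("dataset has no train/test partition; see split_dataset()",
         call. = FALSE)
  }
  if (sum(mask) == 0L) stop("mask must select at least one feature",
                            call. = FALSE)
  sel <- which(mask == 1L)
  tr <- dataset$features[dataset$train, sel, drop = FALSE]
  te <- dataset$features[dataset$test, sel, drop = FALSE]
  pred <- knn_predict(tr, dataset$labels[dataset$train], te, k)
  mean(pred != dataset$labels[dataset$test])
}

#' Wrapper fitness configuration
#'
#' @param alpha Weight of the classification error term, in `[0, 1]`;
#'   protocol default 0.99. The subset-size weight is `1 - alpha`.
#' @param k KNN neighbour count; protocol default 5.
#' @return An object of class `"fitness_config"`.
#' @export
fitness_config <- function(alpha = 0.99, k = 5) {
  stopifnot(alpha >= 0, alpha <= 1, k >= 1)
  structure(list(alpha = alpha, beta = 1 - alpha, k = as.integer(k)),
            class = "fitness_config")
}

#' Decode a position into a guaranteed non-empty mask
#'
#' Thresholds at 0.5; if no coordinate reaches the threshold, the single
#' highest-valued coordinate is selected (ties to the lowest index).
#' Unlike [repair_mask()] this repair is a pure function of the position,
#' which keeps the wrapper objective deterministic and the reported mask
#' consistent with the reported fitness.
#'
#' @param position Continuous position of length D.
#' @return Integer 0/1 vector with at least one bit set.
#' @export
decode_position <- function(position) {
  mask <- binarize_mask(position)
  if (sum(mask) == 0L) mask[which.max(position)] <- 1L
  mask
}

#' Wrapper fitness of a continuous position
#'
#' Decodes the position with [decode_position()] and returns
#' `alpha * error + (1 - alpha) * |Selected| / |ALL|`, where `error` is the
#' held-out KNN misclassification rate of the selected subset. Lies in
#' `[0, 1]`; minimized, and a deterministic function of
#' `(dataset, position, config)`.
#'
#' @param dataset A partitioned [labeled_dataset()].
#' @param position Continuous position of length D.
#' @param config A [fitness_config()].
#' @return Fitness value in `[0, 1]`.
#' @export
evaluate_fitness <- function(dataset, position, config = fitness_config()) {
  mask <- decode_position(position)
  err <- knn_error_rate(dataset, mask, config$k)
  config$alpha * err + config$beta * (sum(mask) / length(mask))
}

#' Stratified train/test split
#'
#' Random partition with per-class stratification at the requested
#' fraction; rounding guarantees every class keeps at least one training
#' sample (a single-sample class is forced into training with a warning).
#' Consumes the R RNG; seed the caller for reproducibility.
#'
#' @param dataset A [labeled_dataset()] (partition, if any, is replaced).
#' @param train_fraction Fraction of samples used for training, in (0, 1);
#'   protocol default 0.7.
#' @return The dataset with `train`/`test` index sets filled in.
#' @export
split_dataset <- function(dataset, train_fraction = 0.7) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            train_fraction > 0, train_fraction < 1)
  y <- dataset$labels
  k <- length(dataset$label_levels)
  n_c <- tabulate(y, k)
  singletons <- n_c == 1L
  if (any(singletons)) {
    warning(sprintf(
      "class %s has a single sample; forced into the training set",
      paste(dataset$label_levels[singletons], collapse = ", ")),
      call. = FALSE)
  }
  # largest-remainder allocation: per-class floors, then top up the
  # classes with the largest fractional parts until the overall target
  # round(fraction * n) is met, keeping 1 <= n_train_c <= n_c - 1
  target <- round(train_fraction * sum(n_c))
  base <- pmin(pmax(floor(train_fraction * n_c), 1L), pmax(n_c - 1L, 1L))
  base[singletons] <- 1L
  room <- ifelse(singletons, 0L, pmax(n_c - 1L - base, 0L))
  short <- target - sum(base)
  frac_part <- train_fraction * n_c - floor(train_fraction * n_c)
  for (cls in order(-frac_part, seq_len(k))) {
    if (short <= 0L) break
    add <- min(room[cls], short)
    base[cls] <- base[cls] + add
    short <- short - add
  }
  train <- integer(0)
  for (cls in seq_len(k)) {
    idx <- which(y == cls)
    picked <- if (base[cls] >= length(idx)) idx else
      sample(idx, base[cls])
    train <- c(train, picked)
  }
  train <- sort(train)
  labeled_dataset(dataset$features, dataset$label_levels[dataset$labels],
                  train = train,
                  test = setdiff(seq_len(nrow(dataset$features)), train))
}

#' Select features with a chimp optimizer
#'
#' Runs CHoA or SOSCHoA over the continuous cube `[0, 1]^D` with the
#' wrapper fitness of [evaluate_fitness()] and decodes the best position
#' into a feature subset.
#'
#' @param dataset A [labeled_dataset()]; split with [split_dataset()]
#'   first (or pass `train_fraction` to have it split here, consuming the
#'   seeded RNG).
#' @param method `"soschoa"` (default) or `"choa"`.
#' @param n_pop,t_max,seed,opposition_mode Passed to the optimizer;
#'   protocol defaults N = 10, t_max = 100.
#' @param config A [fitness_config()].
#' @param train_fraction If the dataset is unpartitioned, fraction for
#'   [split_dataset()] (default 0.7).
#' @return An object of class `"fs_result"`: `mask`, `mask_string`,
#'   `selected` (1-based indices), `n_selected`, `fitness`, `error_rate`,
#'   `accuracy`, and the underlying `run` record.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_samples = 40, n_classes = 2,
#'   n_informative = 3, n_redundant = 2, n_noise = 5, seed = 7))
#' res <- select_features(ds$dataset, t_max = 15, seed = 7)
#' res$selected
#' @export
select_features <- function(dataset, method = c("soschoa", "choa"),
                            n_pop = 10, t_max = 100, seed = NULL,
                            config = fitness_config(),
                            train_fraction = 0.7,
                            opposition_mode = "per-individual") {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "labeled_dataset"))
  with_local_seed(seed, {
    if (is.null(dataset$train)) {
      dataset <- split_dataset(dataset, train_fraction)
    }
    D <- ncol(dataset$features)
    space <- search_space(D, 0, 1)
    objective <- function(pos) evaluate_fitness(dataset, pos, config)
    run <- if (method == "soschoa") {
      soschoa_optimize(objective, space, n_pop, t_max,
                       opposition_mode = opposition_mode)
    } else {
      choa_optimize(objective, space, n_pop, t_max)
    }
    mask <- decode_position(run$best_position)
    err <- knn_error_rate(dataset, mask, config$k)
    structure(list(
      mask = mask,
      mask_string = mask_string(mask),
      selected = which(mask == 1L),
      n_selected = sum(mask),
      fitness = run$best_fitness,
      error_rate = err,
      accuracy = 1 - err,
      method = method, seed = seed,
      dataset = dataset, run = run), class = "fs_result")
  })
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("<feature selection result> method = %s\n", x$method))
  cat(sprintf("  selected %d / %d features\n",
              x$n_selected, length(x$mask)))
  cat(sprintf("  fitness = %.5f, held-out accuracy = %.2f%%\n",
              x$fitness, 100 * x$accuracy))
  if (length(x$mask) <= 60) cat("  mask:", x$mask_string, "\n")
  invisible(x)
}
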