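#' Specification of a synthetic microarray-like dataset
#'
#' Emulates the shape of public high-dimensional gene-expression
#' benchmarks: few samples, many features, a small planted set of
#' class-informative features plus redundant copies and independent noise
#' features.
#'
#' @param n_samples Number of samples; default 100 (benchmarks range
#'   roughly 60-210).
#' @param n_classes Number of class labels (2-11 in the benchmarks);
#'   default 2. Requires `n_samples >= 2 * n_classes`.
#' @param n_informative Planted class-informative features; default 10.
#' @param n_redundant Noisy copies of informative features; default 20.
#' @param n_noise Label-independent standard-Gaussian features; default
#'   170 (so D defaults to 200).
#' @param separation Class-mean offset of informative features, in units
#'   of the within-class standard deviation (1); default 3, a strong
#'   signal a KNN wrapper can exploit.
#' @param redundancy_noise Standard deviation of the noise added to
#'   redundant copies; default 0.5 (parent-child correlation around 0.9).
#' @param informative_pattern `"random"` (default): each informative
#'   feature elevates a random nonempty proper subset of classes.
#'   `"marker"`: informative feature h elevates only class
#'   `(h - 1) %% n_classes + 1`, the marker-gene structure in which every
#'   planted feature carries class information no other feature provides.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the spec.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples = 100, n_classes = 2,
                           n_informative = 10, n_redundant = 20,
                           n_noise = 170, separation = 3,
                           redundancy_noise = 0.5,
                           informative_pattern = c("random", "marker"),
                           seed = 1) {
  informative_pattern <- match.arg(informative_pattern)
  stopifnot(n_samples >= 2 * n_classes, n_classes >= 2,
            n_informative >= 1, n_redundant >= 0, n_noise >= 0,
            separation >= 0, redundancy_noise >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 separation = separation,
                 redundancy_noise = redundancy_noise,
                 informative_pattern = informative_pattern,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Strong-signal recovery preset
#'
#' The preset used by the feature-recovery property: 100 samples, 200
#' features of which 10 are planted marker genes (one per class, 10
#' classes, separation 4, no redundant copies, 190 noise features).
#' Marker structure makes every planted feature necessary: dropping any
#' two merges two classes, so a feature-recovery test is well-posed --
#' with redundant copies or mutually substitutable informative features,
#' recall of the planted set would be ill-defined.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
strong_signal_preset <- function(seed = 1) {
  synthetic_spec(n_samples = 100, n_classes = 10, n_informative = 10,
                 n_redundant = 0, n_noise = 190, separation = 4,
                 informative_pattern = "marker", seed = seed)
}

#' Generate a synthetic labeled dataset with planted structure
#'
#' Class labels are assigned in (near-)balanced blocks. Each informative
#' feature is class-conditionally Gaussian with unit variance: a random
#' nonempty proper subset of classes has mean `separation`, the rest mean
#' 0, so every informative feature separates at least one class pair by
#' exactly the stated amount. Redundant features copy a random informative
#' feature plus Gaussian noise at `redundancy_noise`. Noise features are
#' standard Gaussian, independent of the labels. Columns are then shuffled
#' and the ground-truth roles recorded.
#'
#' @param spec A [synthetic_spec()].
#' @return List with fields `dataset` (a [labeled_dataset()], no
#'   partition), `informative`, `redundant`, `noise` (column indices after
#'   shuffling) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    k <- spec$n_classes
    y <- sort(rep(seq_len(k), length.out = n))
    D <- spec$n_informative + spec$n_redundant + spec$n_noise

    # informative block: class-conditional means 0 or `separation`
    informative <- matrix(stats::rnorm(n * spec$n_informative), n)
    for (h in seq_len(spec$n_informative)) {
      hi <- if (spec$informative_pattern == "marker") {
        (h - 1L) %% k + 1L
      } else {
        sample.int(k, sample.int(k - 1L, 1L))   # nonempty proper subset
      }
      informative[, h] <- informative[, h] +
        spec$separation * (y %in% hi)
    }

    redundant <- NULL
    parents <- integer(0)
    if (spec$n_redundant > 0) {
      parents <- sample.int(spec$n_informative, spec$n_redundant,
                            replace = TRUE)
      redundant <- informative[, parents, drop = FALSE] +
        matrix(stats::rnorm(n * spec$n_redundant,
                            sd = spec$redundancy_noise), n)
    }
    noise <- if (spec$n_noise > 0) {
      matrix(stats::rnorm(n * spec$n_noise), n)
    }

    X <- cbind(informative, redundant, noise)
    roles <- rep(c("informative", "redundant", "noise"),
                 c(spec$n_informative, spec$n_redundant, spec$n_noise))
    perm <- sample.int(D)
    X <- X[, perm, drop = FALSE]
    roles <- roles[perm]
    colnames(X) <- sprintf("f%d", seq_len(D))

    list(dataset = labeled_dataset(X, y),
         informative = which(roles == "informative"),
         redundant = which(roles == "redundant"),
         noise = which(roles == "noise"),
         spec = spec)
  })
}

#' Worked 9-feature encoding example
#'
#' The canonical dimension-9 feature-selection solution used to illustrate
#' the binary encoding: mask `"110100110"`, i.e. features 1, 2, 4, 7 and 8
#' selected and 3, 5, 6, 9 not selected.
#'
#' @return List with `mask` (integer 0/1 vector), `mask_string`,
#'   `selected` and `unselected` (1-based indices), and `dimension`.
#' @export
mask_encoding_example <- function() {
  mask <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L)
  list(mask = mask,
       mask_string = mask_string(mask),
       selected = which(mask == 1L),
       unselected = which(mask == 0L),
       dimension = length(mask))
}
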