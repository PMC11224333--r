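#' Population diversity
#'
#' Mean Euclidean distance of the individuals to the population centroid:
#' zero iff the population has collapsed to a single point, and invariant
#' under translation of all positions.
#'
#' @param positions N x D matrix of positions.
#' @return Non-negative scalar.
#' @export
diversity <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1L)
  if (nrow(positions) < 1L) stop("population must be non-empty",
                                 call. = FALSE)
  centroid <- colMeans(positions)
  mean(sqrt(rowSums(sweep(positions, 2, centroid)^2)))
}

#' Summarize repeated feature-selection runs
#'
#' Computes the repeated-run statistics of the evaluation protocol:
#' mean/max/min accuracy, mean selected-feature count, mean final fitness,
#' and dispersion. The headline `SD` (accuracy) and `Std` (fitness) follow
#' the protocol's printed form \eqn{\frac{1}{M}\sum (x_i - \bar x)^2} —
#' a population variance, not a square-rooted deviation; conventional
#' square-rooted values are also emitted as `SD_conventional` /
#' `Std_conventional`.
#'
#' @param accuracy,n_selected,fitness Numeric vectors of per-run held-out
#'   accuracy, selected-feature count and final fitness (equal length
#'   M >= 1).
#' @return A list of summary statistics with class `"run_summary"`.
#' @export
summarize_runs <- function(accuracy, n_selected, fitness) {
  M <- length(accuracy)
  if (M < 1L) stop("at least one run is required", call. = FALSE)
  stopifnot(length(n_selected) == M, length(fitness) == M)
  pop_var <- function(x) mean((x - mean(x))^2)
  structure(list(
    M = M,
    AccMean = mean(accuracy),
    MaxAcc = max(accuracy),
    MinAcc = min(accuracy),
    SD = pop_var(accuracy),
    SD_conventional = sqrt(pop_var(accuracy)),
    NumMean = mean(n_selected),
    FitMean = mean(fitness),
    Std = pop_var(fitness),
    Std_conventional = sqrt(pop_var(fitness))
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run summary> M = %d runs\n", x$M))
  cat(sprintf("  accuracy: mean %.4f, max %.4f, min %.4f, SD %.3e\n",
              x$AccMean, x$MaxAcc, x$MinAcc, x$SD))
  cat(sprintf("  features: mean %.2f selected\n", x$NumMean))
  cat(sprintf("  fitness:  mean %.5f, Std %.3e\n", x$FitMean, x$Std))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution when the combined sample
#' size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. Two-sided p-values
#' use the doubling rule, capped at 1.
#'
#' @param a,b Non-empty numeric samples.
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])  # rank sum of sample a

  if (!ties && n <= 20L) {
    # exact: enumerate all C(n, na) allocations of ranks to sample a
    sums <- colSums(utils::combn(n, na))
    p_le <- mean(sums <= w)
    p_ge <- mean(sums >= w)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- na * (n + 1) / 2
  tie_counts <- table(pooled)
  sigma2 <- na * nb / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Run the repeated-run evaluation protocol
#'
#' Executes `M` independent seeded feature-selection runs per optimizer on
#' the same dataset, each with a fresh stratified train/test split and a
#' fresh population (per-run seed = `master_seed + run - 1`), and reports
#' per-run records, summaries, and pairwise Wilcoxon rank-sum p-values on
#' the final fitness values.
#'
#' @param dataset An unpartitioned [labeled_dataset()].
#' @param methods Character vector of optimizers to compare, from
#'   `c("soschoa", "choa")`.
#' @param M Number of repeated runs; protocol default 30.
#' @param n_pop,t_max Optimizer protocol parameters (defaults 10 and 100).
#' @param master_seed Base seed for the per-run seed counter.
#' @param config A [fitness_config()].
#' @param train_fraction Training fraction for each run's split.
#' @return An object of class `"experiment"`: per-method `runs` (list of
#'   `fs_result`), `records` (data frame of per-run accuracy, selected
#'   count, fitness), `summaries`, and `p_values` (pairwise rank-sum on
#'   final fitness).
#' @export
run_experiment <- function(dataset, methods = c("soschoa", "choa"),
                           M = 30, n_pop = 10, t_max = 100,
                           master_seed = 1, config = fitness_config(),
                           train_fraction = 0.7) {
  stopifnot(M >= 1, all(methods %in% c("soschoa", "choa")))
  runs <- list(); records <- list(); summaries <- list()
  for (m in methods) {
    rs <- lapply(seq_len(M), function(i) {
      select_features(dataset, method = m, n_pop = n_pop, t_max = t_max,
                      seed = master_seed + i - 1L, config = config,
                      train_fraction = train_fraction)
    })
    runs[[m]] <- rs
    records[[m]] <- data.frame(
      method = m,
      run = seq_len(M),
      seed = master_seed + seq_len(M) - 1L,
      accuracy = vapply(rs, `[[`, numeric(1), "accuracy"),
      n_selected = vapply(rs, function(r) as.numeric(r$n_selected),
                          numeric(1)),
      fitness = vapply(rs, `[[`, numeric(1), "fitness"))
    summaries[[m]] <- summarize_runs(records[[m]]$accuracy,
                                     records[[m]]$n_selected,
                                     records[[m]]$fitness)
  }
  p_values <- NULL
  if (length(methods) > 1L) {
    pairs <- utils::combn(methods, 2)
    p_values <- data.frame(
      method_a = pairs[1, ], method_b = pairs[2, ],
      p_value = apply(pairs, 2, function(pr) {
        wilcoxon_rank_sum(records[[pr[1]]]$fitness,
                          records[[pr[2]]]$fitness)
      }))
  }
  structure(list(runs = runs, records = do.call(rbind, records),
                 summaries = summaries, p_values = p_values,
                 config = list(methods = methods, M = M, n_pop = n_pop,
                               t_max = t_max, master_seed = master_seed,
                               alpha = config$alpha, k = config$k,
                               train_fraction = train_fraction)),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment> M = %d runs x {%s}\n", x$config$M,
              paste(x$config$methods, collapse = ", ")))
  for (m in names(x$summaries)) {
    s <- x$summaries[[m]]
    cat(sprintf("  %-8s AccMean %.2f%%  MaxAcc %.2f%%  NumMean %.2f  FitMean %.5f\n",
                m, 100 * s$AccMean, 100 * s$MaxAcc, s$NumMean, s$FitMean))
  }
  if (!is.null(x$p_values)) {
    for (i in seq_len(nrow(x$p_values))) {
      cat(sprintf("  rank-sum %s vs %s: p = %.4g\n",
                  x$p_values$method_a[i], x$p_values$method_b[i],
                  x$p_values$p_value[i]))
    }
  }
  invisible(x)
}
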