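# Shared optimizer infrastructure: search spaces, population state,
# evaluation with counters, elitist recording.

#' Define a bounded continuous search space
#'
#' @param dims Number of dimensions `D >= 1`.
#' @param lower,upper Per-dimension bounds (length 1 or `dims`),
#'   `lower < upper` element-wise.
#' @return An object of class `"search_space"` with fields `dims`, `lower`,
#'   `upper`.
#' @export
search_space <- function(dims, lower = 0, upper = 1) {
  stopifnot(length(dims) == 1L, dims >= 1)
  dims <- as.integer(dims)
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper element-wise",
         call. = FALSE)
  }
  structure(list(dims = dims, lower = lower, upper = upper),
            class = "search_space")
}

clamp_positions <- function(positions, space) {
  # hard clamp, row-wise positions (N x D)
  lo <- matrix(space$lower, nrow(positions), space$dims, byrow = TRUE)
  hi <- matrix(space$upper, nrow(positions), space$dims, byrow = TRUE)
  pmin(pmax(positions, lo), hi)
}

init_population <- function(n_pop, space) {
  D <- space$dims
  u <- matrix(stats::runif(n_pop * D), n_pop, D)
  sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

# Evaluate all rows of `positions`; errors name the offending individual.
evaluate_all <- function(positions, objective, counters = NULL) {
  n <- nrow(positions)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    fit[i] <- objective(positions[i, ])
    if (!is.finite(fit[i])) {
      stop(sprintf("objective returned a non-finite value for individual %d",
                   i), call. = FALSE)
    }
  }
  if (!is.null(counters)) counters$evals <- counters$evals + n
  fit
}

evaluate_one <- function(x, objective, i, counters = NULL) {
  f <- objective(x)
  if (!is.finite(f)) {
    stop(sprintf("objective returned a non-finite value for individual %d", i),
         call. = FALSE)
  }
  if (!is.null(counters)) counters$evals <- counters$evals + 1L
  f
}

new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$evals <- 0L   # objective evaluations
  e$ops <- 0      # element-wise vector-operation units (each counts D work)
  e
}

# Run an RNG-consuming expression under a local seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_run_state <- function(positions, fitnesses, t_max) {
  best <- which.min(fitnesses)
  list(
    best_position = positions[best, ],
    best_fitness = fitnesses[best],
    convergence = c(fitnesses[best], rep(NA_real_, t_max)),
    diversity = c(diversity(positions), rep(NA_real_, t_max)),
    evals_per_gen = rep(NA_real_, t_max),
    ops_per_gen = rep(NA_real_, t_max)
  )
}

record_generation <- function(state, g, positions, fitnesses,
                              gen_evals, gen_ops) {
  best <- which.min(fitnesses)
  if (fitnesses[best] < state$best_fitness) {
    state$best_fitness <- fitnesses[best]
    state$best_position <- positions[best, ]
  }
  state$convergence[g + 1L] <- state$best_fitness
  state$diversity[g + 1L] <- diversity(positions)
  state$evals_per_gen[g] <- gen_evals
  state$ops_per_gen[g] <- gen_ops
  state
}

finish_run <- function(state, method, n_pop, t_max, seed, counters) {
  structure(
    list(best_position = state$best_position,
         best_fitness = state$best_fitness,
         convergence = state$convergence,
         diversity = state$diversity,
         evals_per_gen = state$evals_per_gen,
         ops_per_gen = state$ops_per_gen,
         total_evals = counters$evals,
         method = method, n_pop = n_pop, t_max = t_max, seed = seed),
    class = "chimp_run")
}

#' @export
print.chimp_run <- function(x, ...) {
  cat(sprintf("<%s run> N = %d, t_max = %d, seed = %s\n",
              toupper(x$method), x$n_pop, x$t_max,
              if (is.null(x$seed)) "NULL" else x$seed))
  cat(sprintf("  best fitness: %.6g (after %d objective evaluations)\n",
              x$best_fitness, x$total_evals))
  invisible(x)
}
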