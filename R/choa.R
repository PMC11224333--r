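#' Convergence factor of the chimp position update
#'
#' Decreases from 2.5 at `t = 0` to 0 at `t = t_max`:
#' \eqn{f = 2.5 - 2.5 t / t_{max}}. It bounds the step coefficient `a`
#' (drawn from \eqn{[-f, f]}), so steps shrink as the run progresses.
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Maximum iteration count, `>= 1`.
#' @return The convergence factor, a number in `[0, 2.5]`.
#' @examples
#' compute_f(0, 100)    # 2.5
#' compute_f(100, 100)  # 0
#' @export
compute_f <- function(t, t_max) {
  stopifnot(length(t) == 1L, length(t_max) == 1L, t_max >= 1)
  if (t < 0 || t > t_max) {
    stop("`t` must lie in [0, t_max]", call. = FALSE)
  }
  2.5 - 2.5 * t / t_max
}

#' Sample the stochastic coefficients of one position update
#'
#' For each of the four leaders k: \eqn{a_k = 2 f r_1 - f} with
#' \eqn{r_1 \sim U[0,1]} (so \eqn{a_k \in [-f, f]}), \eqn{C_k = 2 r_2}
#' with \eqn{r_2 \sim U[0,1]} (so \eqn{C_k \in [0, 2]}), and
#' \eqn{m_k \in [0, 1]} drawn from the individual's sine-chaos stream.
#' Consumes the R RNG; call inside a seeded context for reproducibility.
#'
#' @param f Convergence factor in `[0, 2.5]`.
#' @param chaos The individual's [chaos_stream()].
#' @return List with numeric length-4 fields `a`, `C`, `m`.
#' @export
sample_coefficients <- function(f, chaos) {
  stopifnot(f >= 0, f <= 2.5)
  list(a = 2 * f * stats::runif(4) - f,
       C = 2 * stats::runif(4),
       m = chaotic_value(chaos, 4L))
}

#' Select the four leaders of a population
#'
#' The four lowest-fitness individuals, in order: attacker, barrier,
#' chaser, driver. Ties are broken by lower individual index.
#'
#' @param positions N x D matrix of candidate positions.
#' @param fitnesses Length-N fitness vector (minimized).
#' @return List with fields `positions` (4 x D matrix, rows ordered
#'   attacker..driver), `fitnesses` (length 4) and `indices`.
#' @export
select_leaders <- function(positions, fitnesses) {
  n <- nrow(positions)
  if (n < 4L) stop("leader selection needs at least 4 individuals",
                   call. = FALSE)
  stopifnot(length(fitnesses) == n)
  ord <- order(fitnesses, seq_len(n))[1:4]
  list(positions = positions[ord, , drop = FALSE],
       fitnesses = fitnesses[ord],
       indices = ord)
}

#' One leader-guided candidate position
#'
#' The chase/attack model: \eqn{X_k = leader - a_k |C_k \cdot leader -
#' m_k \cdot x|}, evaluated element-wise.
#'
#' @param x Current position.
#' @param leader Leader position (same length).
#' @param a,C,m Scalar coefficients for this leader.
#' @return The guided candidate position.
#' @export
leader_guided_position <- function(x, leader, a, C, m) {
  if (length(x) != length(leader)) {
    stop("`x` and `leader` must have the same dimension", call. = FALSE)
  }
  leader - a * abs(C * leader - m * x)
}

#' Aggregate the four leader-guided candidates
#'
#' Element-wise mean \eqn{(X_1 + X_2 + X_3 + X_4)/4}.
#'
#' @param x1,x2,x3,x4 Candidate positions of equal length.
#' @return The aggregated position.
#' @export
aggregate_position <- function(x1, x2, x3, x4) {
  d <- lengths(list(x1, x2, x3, x4))
  if (length(unique(d)) != 1L) {
    stop("candidate positions must have equal dimensions", call. = FALSE)
  }
  (x1 + x2 + x3 + x4) / 4
}

#' Stochastic position update of one individual
#'
#' With probability 1/2 (switch `u < 0.5`) the individual moves to the
#' aggregate of the four leader-guided candidates; otherwise it relocates
#' chaotically, each coordinate set to
#' `lower + (upper - lower) * chaotic value`. The result is clamped into
#' the search space.
#'
#' @param x Current position.
#' @param leaders A leader set from [select_leaders()].
#' @param coeff Coefficients from [sample_coefficients()].
#' @param u Switch draw in `[0, 1]`.
#' @param chaos The individual's [chaos_stream()].
#' @param space A [search_space()].
#' @return The updated, clamped position.
#' @export
stochastic_position_update <- function(x, leaders, coeff, u, chaos, space) {
  if (!is.finite(u) || u < 0 || u > 1) {
    stop("`u` must lie in [0, 1]", call. = FALSE)
  }
  if (u < 0.5) {
    xs <- lapply(1:4, function(k) {
      leader_guided_position(x, leaders$positions[k, ],
                             coeff$a[k], coeff$C[k], coeff$m[k])
    })
    pos <- aggregate_position(xs[[1]], xs[[2]], xs[[3]], xs[[4]])
  } else {
    pos <- space$lower +
      (space$upper - space$lower) * chaotic_value(chaos, space$dims)
  }
  pmin(pmax(pos, space$lower), space$upper)
}

# One CHoA generation over an evaluated population (internal engine body).
choa_generation <- function(positions, fitnesses, objective, f, chaos_streams,
                            space, counters) {
  n <- nrow(positions)
  leaders <- select_leaders(positions, fitnesses)
  new_pos <- positions
  for (i in seq_len(n)) {
    coeff <- sample_coefficients(f, chaos_streams[[i]])
    u <- stats::runif(1)
    new_pos[i, ] <- stochastic_position_update(
      positions[i, ], leaders, coeff, u, chaos_streams[[i]], space)
  }
  # 4 guided candidates + aggregate + clamp per individual, each O(D)
  counters$ops <- counters$ops + n * 6 * space$dims
  fit <- evaluate_all(new_pos, objective, counters)
  list(positions = new_pos, fitnesses = fit)
}

#' One full CHoA generation
#'
#' Recomputes the convergence factor, redraws per-individual coefficients,
#' updates every position through [stochastic_position_update()], clamps,
#' and re-evaluates.
#'
#' @param positions,fitnesses Evaluated population (N x D matrix, length-N
#'   vector), N >= 4.
#' @param objective Function mapping a position to a finite fitness
#'   (minimized).
#' @param t,t_max Current and maximum iteration (for the convergence
#'   factor).
#' @param chaos_streams List of N [chaos_stream()]s, one per individual.
#' @param space A [search_space()].
#' @return List with updated `positions` and `fitnesses`.
#' @export
choa_step <- function(positions, fitnesses, objective, t, t_max,
                      chaos_streams, space) {
  f <- compute_f(t, t_max)
  choa_generation(positions, fitnesses, objective, f, chaos_streams,
                  space, new_counters())
}

#' Run the baseline Chimp Optimization Algorithm
#'
#' Continuous bounded minimization with population size `n_pop` over
#' `t_max` generations, with elitist best-ever recording. The run is fully
#' determined by `seed`.
#'
#' @param objective Function mapping a length-D numeric position to a
#'   finite fitness value (minimized).
#' @param space A [search_space()].
#' @param n_pop Population size (>= 4); protocol default 10.
#' @param t_max Number of generations; protocol default 100.
#' @param seed Integer seed, or `NULL` to consume the global RNG stream.
#' @param chaos_control Sine-map control parameter in `(0, 1]`.
#' @return A `"chimp_run"` object: `best_position`, `best_fitness`,
#'   `convergence` and `diversity` curves of length `t_max + 1`,
#'   per-generation `evals_per_gen` / `ops_per_gen` counters.
#' @examples
#' sp <- search_space(2, -5, 5)
#' run <- choa_optimize(function(x) sum(x^2), sp, n_pop = 10,
#'                      t_max = 25, seed = 1)
#' run$best_fitness
#' @export
choa_optimize <- function(objective, space, n_pop = 10, t_max = 100,
                          seed = NULL, chaos_control = 1) {
  stopifnot(n_pop >= 4, t_max >= 0)
  with_local_seed(seed, {
    counters <- new_counters()
    positions <- init_population(n_pop, space)
    streams <- lapply(stats::runif(n_pop, 0.05, 0.95), chaos_stream,
                      control = chaos_control)
    fitnesses <- evaluate_all(positions, objective, counters)
    state <- new_run_state(positions, fitnesses, t_max)
    for (g in seq_len(t_max)) {
      e0 <- counters$evals; o0 <- counters$ops
      gen <- choa_generation(positions, fitnesses, objective,
                             compute_f(g, t_max), streams, space, counters)
      positions <- gen$positions
      fitnesses <- gen$fitnesses
      state <- record_generation(state, g, positions, fitnesses,
                                 counters$evals - e0, counters$ops - o0)
    }
    finish_run(state, "choa", n_pop, t_max, seed, counters)
  })
}
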