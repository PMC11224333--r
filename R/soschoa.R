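#' Social-coevolution position update
#'
#' Pulls individual i toward the attacker relative to the "co-occurrence"
#' midpoint of itself and a neighbour, scaled by the benefit factor R:
#' \eqn{x_i' = x_i + r_3 (attacker - \frac{x_i + x_{prev}}{2} R)}.
#' R = 1 models a small mutual benefit from the interaction, R = 2 a large
#' one.
#'
#' @param x_i Current position of individual i.
#' @param x_prev Position of its ring neighbour (individual i - 1, with the
#'   first individual paired to the last).
#' @param attacker Position of the best individual.
#' @param r3 Uniform draw in `[0, 1]`.
#' @param benefit Benefit factor, 1 or 2.
#' @return The updated (unclamped) position.
#' @export
social_coevolution_update <- function(x_i, x_prev, attacker, r3, benefit) {
  if (!benefit %in% c(1, 2)) {
    stop("`benefit` must be 1 or 2", call. = FALSE)
  }
  if (length(unique(lengths(list(x_i, x_prev, attacker)))) != 1L) {
    stop("positions must have equal dimensions", call. = FALSE)
  }
  if (!is.finite(r3) || r3 < 0 || r3 > 1) {
    stop("`r3` must lie in [0, 1]", call. = FALSE)
  }
  co_occurrence <- (x_i + x_prev) / 2
  x_i + r3 * (attacker - co_occurrence * benefit)
}

#' Dynamic opposition bounds of a population
#'
#' Per-dimension population minimum and maximum; as the population
#' converges, the bounds contract onto the common point, which makes the
#' sine-opposition candidate a fixed point there.
#'
#' @param positions N x D matrix, N >= 1.
#' @return List with numeric length-D fields `lower` and `upper`.
#' @export
dynamic_bounds <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1L)
  if (nrow(positions) < 1L) stop("population must be non-empty",
                                 call. = FALSE)
  list(lower = apply(positions, 2, min), upper = apply(positions, 2, max))
}

#' Dimension-wise sine-chaotic opposition sweep with greedy replacement
#'
#' For each targeted individual an opposition candidate is built dimension
#' by dimension as `lb_j + (ub_j - x_j) * s_j`, with `lb`/`ub` the dynamic
#' population bounds and `s_j` drawn from the individual's sine-chaos
#' stream. The candidate replaces the original iff its fitness is no worse
#' (greedy selection), so fitnesses never worsen individual-wise.
#'
#' @param positions,fitnesses Evaluated population.
#' @param objective Fitness function (minimized).
#' @param chaos_streams List of per-individual [chaos_stream()]s.
#' @param targets Indices of individuals to sweep; defaults to all.
#' @param counters Internal instrumentation environment (optional).
#' @return List with updated `positions` and `fitnesses`.
#' @export
sine_opposition_sweep <- function(positions, fitnesses, objective,
                                  chaos_streams,
                                  targets = seq_len(nrow(positions)),
                                  counters = NULL) {
  bounds <- dynamic_bounds(positions)
  D <- ncol(positions)
  for (i in targets) {
    s <- chaotic_value(chaos_streams[[i]], D)
    cand <- bounds$lower + (bounds$upper - positions[i, ]) * s
    f_cand <- evaluate_one(cand, objective, i, counters)
    if (greedy_select(fitnesses[i], f_cand)) {
      positions[i, ] <- cand
      fitnesses[i] <- f_cand
    }
  }
  if (!is.null(counters)) {
    counters$ops <- counters$ops + length(targets) * 2 * D
  }
  list(positions = positions, fitnesses = fitnesses)
}

# One SOSCHoA generation: social coevolution sweep (synchronous, ring
# topology), clamp + evaluate, leader refresh, sine-chaotic opposition
# sweep under greedy replacement.
soschoa_generation <- function(positions, fitnesses, objective, f,
                               chaos_streams, space, opposition_mode,
                               counters) {
  n <- nrow(positions)
  leaders <- select_leaders(positions, fitnesses)
  attacker <- leaders$positions[1, ]
  snapshot <- positions
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    positions[i, ] <- social_coevolution_update(
      snapshot[i, ], snapshot[prev, ], attacker,
      r3 = stats::runif(1), benefit = sample(1:2, 1L))
  }
  positions <- clamp_positions(positions, space)
  counters$ops <- counters$ops + n * 3 * space$dims
  fitnesses <- evaluate_all(positions, objective, counters)

  targets <- if (opposition_mode == "best-only") {
    which.min(fitnesses)
  } else {
    seq_len(n)
  }
  sine_opposition_sweep(positions, fitnesses, objective, chaos_streams,
                        targets, counters)
}

#' One full SOSCHoA generation
#'
#' @inheritParams choa_step
#' @param opposition_mode `"per-individual"` (default) sweeps every
#'   individual with an opposition candidate; `"best-only"` perturbs only
#'   the current best.
#' @return List with updated `positions` and `fitnesses`.
#' @export
soschoa_step <- function(positions, fitnesses, objective, t, t_max,
                         chaos_streams, space,
                         opposition_mode = c("per-individual", "best-only")) {
  opposition_mode <- match.arg(opposition_mode)
  f <- compute_f(t, t_max)  # part of the iteration state; see vignette
  soschoa_generation(positions, fitnesses, objective, f, chaos_streams,
                     space, opposition_mode, new_counters())
}

#' Run the SOSCHoA optimizer
#'
#' CHoA augmented with the social-coevolution position update (replacing
#' the leader-aggregate/chaotic update) and a dimension-wise sine-chaotic
#' opposition sweep under greedy replacement. Same contract and return
#' shape as [choa_optimize()]; the two are interchangeable.
#'
#' @inheritParams choa_optimize
#' @inheritParams soschoa_step
#' @return A `"chimp_run"` object; see [choa_optimize()].
#' @examples
#' sp <- search_space(2, -5, 5)
#' run <- soschoa_optimize(function(x) sum(x^2), sp, n_pop = 10,
#'                         t_max = 25, seed = 1)
#' run$best_fitness
#' @export
soschoa_optimize <- function(objective, space, n_pop = 10, t_max = 100,
                             seed = NULL, chaos_control = 1,
                             opposition_mode = c("per-individual",
                                                 "best-only")) {
  opposition_mode <- match.arg(opposition_mode)
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
      gen <- soschoa_generation(positions, fitnesses, objective,
                                compute_f(g, t_max), streams, space,
                                opposition_mode, counters)
      positions <- gen$positions
      fitnesses <- gen$fitnesses
      state <- record_generation(state, g, positions, fitnesses,
                                 counters$evals - e0, counters$ops - o0)
    }
    finish_run(state, "soschoa", n_pop, t_max, seed, counters)
  })
}
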