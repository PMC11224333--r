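#' Sine chaotic map and opposition-learning primitives
#'
#' The sine map \eqn{S(x) = a \sin(\pi x)} is the single source of chaotic
#' numbers used throughout the package: it modulates the `m` coefficient of
#' the chimp position update, the chaotic-relocation branch of the CHoA
#' update, and the dimension-wise sine-chaotic opposition candidates.
#' For a control parameter \eqn{a \in (0, 1]} and state \eqn{x \in [0, 1]}
#' every iterate lies in \eqn{[0, a]}; feeding the iterate back as the next
#' state keeps the orbit inside \eqn{[0, 1]}.
#'
#' @param state Current map state, a number in \eqn{[0, 1]}.
#' @param control Map control parameter \eqn{a}, a number in \eqn{(0, 1]}.
#' @return `sine_map_step()` returns the next iterate \eqn{a \sin(\pi x)}.
#' @examples
#' sine_map_step(0.5, 1)   # 1
#' sine_map_step(0.25, 1)  # sin(pi/4)
#' @export
sine_map_step <- function(state, control) {
  if (!is.numeric(state) || any(!is.finite(state)) ||
      any(state < 0) || any(state > 1)) {
    stop("`state` must be finite and lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(control) || length(control) != 1L || !is.finite(control) ||
      control <= 0 || control > 1) {
    stop("`control` must be a single number in (0, 1]", call. = FALSE)
  }
  control * sin(pi * state)
}

#' Create a sine-chaos stream
#'
#' A stream is a small mutable state (environment) holding the map control
#' parameter, the current state and the number of values emitted so far.
#' Each optimizer individual owns one independent stream, so a run is fully
#' determined by the seed that drew the initial states.
#'
#' @param init_state Initial state in \eqn{[0, 1]}. The optimizers draw it
#'   uniformly from \eqn{(0.05, 0.95)} to avoid the fixed point at 0 and
#'   states mapping numerically close to it.
#' @param control Control parameter \eqn{a \in (0, 1]}; default 1.
#' @return An object of class `"sine_chaos_stream"`.
#' @seealso [chaotic_value()]
#' @export
chaos_stream <- function(init_state, control = 1) {
  # validate via one dry step
  sine_map_step(init_state, control)
  s <- new.env(parent = emptyenv())
  s$control <- control
  s$state <- init_state
  s$pos <- 0L
  class(s) <- "sine_chaos_stream"
  s
}

#' Draw chaotic values in [0, 1] from a stream
#'
#' Advances the stream `n` steps and returns the iterates rescaled to
#' \eqn{[0, 1]} by dividing by the control parameter. Consumers needing a
#' different range rescale the returned values themselves.
#'
#' @param stream A [chaos_stream()].
#' @param n Number of values to draw.
#' @return Numeric vector of length `n` with entries in \eqn{[0, 1]}.
#' @export
chaotic_value <- function(stream, n = 1L) {
  stopifnot(inherits(stream, "sine_chaos_stream"), n >= 0L)
  out <- numeric(n)
  x <- stream$state
  a <- stream$control
  for (i in seq_len(n)) {
    x <- a * sin(pi * x)
    out[i] <- x
  }
  stream$state <- x
  stream$pos <- stream$pos + as.integer(n)
  out / a
}

#' Opposition point of a value within bounds
#'
#' Classical opposition-based learning reflects a value about the midpoint
#' of its interval: \eqn{\bar x = lb + ub - x}.
#'
#' @param x Value(s) with `lower <= x <= upper`.
#' @param lower,upper Interval bounds (recycled against `x`).
#' @return The opposition point(s) `lower + upper - x`.
#' @examples
#' opposition_point(0.3, 0, 1)  # 0.7
#' @export
opposition_point <- function(x, lower, upper) {
  check_in_bounds(x, lower, upper)
  lower + upper - x
}

#' Sine-chaotic opposition point
#'
#' Opposition modulated by a chaotic factor \eqn{s \in [0, 1]}:
#' \eqn{\bar x = lb + (ub - x) \cdot s}. For any `s` in \eqn{[0, 1]} the
#' result stays inside `[lower, upper]`, and when `lower == upper == x`
#' the point is a fixed point (the collapsed-population limit).
#'
#' @inheritParams opposition_point
#' @param s Chaotic modulation factor(s) in \eqn{[0, 1]}.
#' @return The modulated opposition point(s).
#' @export
sine_opposition_point <- function(x, lower, upper, s) {
  check_in_bounds(x, lower, upper)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("`s` must lie in [0, 1]", call. = FALSE)
  }
  lower + (upper - x) * s
}

#' Greedy selection between an original and an opposition candidate
#'
#' Under minimization the opposition candidate replaces the original iff its
#' fitness is no worse; ties go to the opposition candidate.
#'
#' @param original_fitness,opposition_fitness Finite fitness values.
#' @return `TRUE` if the opposition candidate is kept, `FALSE` otherwise.
#' @export
greedy_select <- function(original_fitness, opposition_fitness) {
  if (!all(is.finite(c(original_fitness, opposition_fitness)))) {
    stop("fitness values must be finite", call. = FALSE)
  }
  opposition_fitness <= original_fitness
}

check_in_bounds <- function(x, lower, upper) {
  if (any(!is.finite(x)) || any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(lower > upper)) {
    stop("`lower` must not exceed `upper`", call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop("`x` must lie within [lower, upper]", call. = FALSE)
  }
  invisible(TRUE)
}
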