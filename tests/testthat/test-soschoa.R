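test_that("social coevolution update follows the co-occurrence formula", {
  x <- c(1, 1)
  expect_identical(social_coevolution_update(x, c(3, 3), c(2, 2),
                                             r3 = 0, benefit = 1), x)
  # converged fixed point at benefit 1
  v <- c(0.4, 0.8)
  expect_equal(social_coevolution_update(v, v, v, r3 = 0.6, benefit = 1), v)
  expect_equal(social_coevolution_update(c(1, 1), c(3, 3), c(2, 2),
                                         r3 = 0.5, benefit = 2), c(0, 0))
  expect_error(social_coevolution_update(x, x, x, 0.5, 3), "benefit")
  expect_error(social_coevolution_update(x, x, c(1, 2, 3), 0.5, 1),
               "dimension")
  expect_error(social_coevolution_update(x, x, x, 1.5, 1), "r3")
})

test_that("dynamic bounds are coordinate-wise population extrema", {
  pos <- rbind(c(0, 5), c(2, 1))
  b <- dynamic_bounds(pos)
  expect_equal(b$lower, c(0, 1))
  expect_equal(b$upper, c(2, 5))
  one <- dynamic_bounds(rbind(c(3, 4)))
  expect_equal(one$lower, one$upper)
  collapsed <- dynamic_bounds(matrix(0.7, 5, 3))
  expect_equal(collapsed$lower, collapsed$upper)
})

test_that("sine opposition sweep is greedy and closed in dynamic bounds", {
  set.seed(21)
  n <- 6; D <- 4
  pos <- matrix(runif(n * D), n, D)
  fit <- apply(pos, 1, quadratic_objective)
  streams <- replicate(n, chaos_stream(runif(1, 0.05, 0.95)),
                       simplify = FALSE)
  out <- sine_opposition_sweep(pos, fit, quadratic_objective, streams)
  # fitnesses never worsen individual-wise
  expect_true(all(out$fitnesses <= fit + 1e-15))
  # accepted candidates lie within the entry bounds
  b <- dynamic_bounds(pos)
  for (i in seq_len(n)) {
    expect_true(all(out$positions[i, ] >= b$lower - 1e-12))
    expect_true(all(out$positions[i, ] <= b$upper + 1e-12))
  }
  # candidate rejected everywhere when the objective punishes moves:
  # positions at distinct minima of an indicator-style objective
  sticky <- function(x) if (all(abs(x - 0.5) < 1e-9)) 0 else 1
  pos2 <- matrix(0.5, n, D); fit2 <- rep(0, n)
  out2 <- sine_opposition_sweep(pos2, fit2, sticky, streams)
  expect_equal(out2$positions, pos2)  # collapsed: candidates equal point
  # collapsed population: candidates equal the point, population unchanged
  pos3 <- matrix(0.25, n, D)
  fit3 <- apply(pos3, 1, quadratic_objective)
  out3 <- sine_opposition_sweep(pos3, fit3, quadratic_objective, streams)
  expect_equal(out3$positions, pos3)
})

test_that("1-D greedy branches: candidate kept iff no worse", {
  streams <- list(chaos_stream(0.5))  # emits s = 1 first
  # x = 1, population bounds [0, 1] via two individuals; only target idx 1
  pos <- rbind(1, 0)
  better_low <- function(x) x        # f(0) = 0 <= f(1) = 1 -> keep
  out <- sine_opposition_sweep(pos, c(1, 0), better_low,
                               list(chaos_stream(0.5), chaos_stream(0.5)),
                               targets = 1L)
  expect_equal(out$positions[1, ], 0)
  worse_low <- function(x) -x       # f(0) = 0 > f(1) = -1 -> reject
  out2 <- sine_opposition_sweep(pos, c(-1, 0), worse_low,
                                list(chaos_stream(0.5), chaos_stream(0.5)),
                                targets = 1L)
  expect_equal(out2$positions[1, ], 1)
})

test_that("soschoa runs are deterministic, monotone, bounded", {
  space <- search_space(4, -3, 3)
  r1 <- soschoa_optimize(quadratic_objective, space, n_pop = 8,
                         t_max = 30, seed = 13)
  r2 <- soschoa_optimize(quadratic_objective, space, n_pop = 8,
                         t_max = 30, seed = 13)
  expect_identical(r1$convergence, r2$convergence)
  expect_length(r1$convergence, 31)
  expect_true(all(diff(r1$convergence) <= 0))
  expect_true(all(r1$best_position >= -3 & r1$best_position <= 3))
  # per-generation objective evaluations <= 2N (social sweep + opposition)
  expect_true(all(r1$evals_per_gen <= 2 * 8))
  # best-only mode evaluates N + 1 per generation
  rb <- soschoa_optimize(quadratic_objective, space, n_pop = 8,
                         t_max = 10, seed = 13,
                         opposition_mode = "best-only")
  expect_identical(rb$evals_per_gen, rep(9, 10))
  # finds the quadratic optimum comfortably
  expect_lt(r1$best_fitness, 1e-3)
})

test_that("a collapsed population with r3 = 0 is a soschoa_step fixed point", {
  # r3 = 0 removes the social move; collapsed bounds fix the opposition
  n <- 5; D <- 3
  pos <- matrix(0.6, n, D)
  fit <- apply(pos, 1, quadratic_objective)
  streams <- replicate(n, chaos_stream(0.3), simplify = FALSE)
  space <- search_space(D, 0, 1)
  # force r3 = 0 by stubbing the RNG draw: equivalent check through the
  # exported op on the collapsed state
  moved <- social_coevolution_update(pos[1, ], pos[2, ], pos[3, ],
                                     r3 = 0, benefit = 2)
  expect_identical(moved, pos[1, ])
  out <- sine_opposition_sweep(pos, fit, quadratic_objective, streams)
  expect_equal(out$positions, pos)
})

test_that("per-generation arithmetic grows linearly in N * D", {
  space_ops <- function(D, n_pop = 6) {
    r <- soschoa_optimize(quadratic_objective, search_space(D, 0, 1),
                          n_pop = n_pop, t_max = 5, seed = 2)
    mean(r$ops_per_gen)
  }
  Ds <- c(10, 20, 40, 80)
  ops <- vapply(Ds, space_ops, numeric(1))
  fit <- stats::lm(ops ~ Ds)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # fit can be exact
  expect_gt(r2, 0.99)
})

test_that("small-scale oracle: soschoa never beats exhaustive enumeration", {
  ds <- make_tiny_dataset(n = 16, D = 5, n_signal = 2, delta = 4, seed = 8)
  set.seed(8)
  ds <- split_dataset(ds)
  enum <- oracle_enumerate_fitness(ds)
  hits <- 0L
  for (s in 1:5) {
    res <- select_features(ds, method = "soschoa", n_pop = 8, t_max = 40,
                           seed = s)
    expect_gte(res$fitness, enum$optimum - 1e-12)
    if (abs(res$fitness - enum$optimum) < 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 3L)  # attains the optimum in most short runs
})
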