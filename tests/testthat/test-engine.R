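# Pattern enumeration, fixed-pattern solves, incremental search.

test_that("pattern enumeration has the right counts and order", {
  expect_length(enumerate_patterns(8, 1), 8L)
  p2 <- enumerate_patterns(8, 2)
  expect_length(p2, 36L)
  expect_equal(sum(vapply(p2, length, 0L) == 2L), 28L)
  expect_length(enumerate_patterns(3, 3), 7L)
  expect_identical(p2[[1]], 1L)
  expect_identical(p2[[9]], c(1L, 2L))
  expect_error(enumerate_patterns(30, 10, max_patterns = 1000),
               "incremental")
  expect_length(enumerate_patterns(8, 2, exact_size = TRUE), 28L)
})

test_that("fixed-pattern solves match an independent grid oracle on toys", {
  # wide metabolite box so the optimum sits at an enzyme-box corner,
  # which the endpoint-including grid hits exactly
  for (seed in c(2, 5)) {
    m <- generate_toy_model(3, branching = TRUE, seed = seed)
    b <- bounds_spec(gamma_e = c(0.5, 2), gamma_b = c(1, 1),
                     gamma_x = c(0.01, 100), zeta_x = Inf, zeta_e = Inf)
    target <- "R3"
    prob <- make_problem(m, b, objective_spec(target), type = "primal")
    free_ids <- c("E1", "E4", "E5")     # inflow, terminal, branch
    mod <- match(free_ids, m$enzymes$id)
    sol <- solve_fixed_pattern(prob, mod, engine_config(n_starts = 8, seed = 3))
    grid_best <- oracle_grid_best(m, free_ids, 0.5, 2, target, n_grid = 9)
    expect_true(sol$feasible)
    expect_equal(unname(sol$flux_ratios[[target]]), grid_best,
                 tolerance = 1e-4)
  }
})

test_that("fixed-pattern solves are deterministic given the seed", {
  m <- generate_toy_model(3, branching = TRUE, seed = 4)
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
  prob <- make_problem(m, b, objective_spec("R3"), type = "primal")
  cfg <- engine_config(n_starts = 6, seed = 42)
  s1 <- solve_fixed_pattern(prob, c(1L, 4L), cfg)
  s2 <- solve_fixed_pattern(prob, c(1L, 4L), cfg)
  expect_identical(s1$enzyme_ratios, s2$enzyme_ratios)
  expect_identical(s1$scalar_objective, s2$scalar_objective)
  expect_identical(s1$state$metabolite_levels, s2$state$metabolite_levels)
})

test_that("more starts never worsen the best objective found", {
  m <- yeast_model()
  b <- yeast_test_bounds()
  prob <- make_problem(m, b, objective_spec("PYK"), type = "primal")
  s1 <- solve_fixed_pattern(prob, c(1L, 3L), engine_config(n_starts = 1, seed = 7))
  s25 <- solve_fixed_pattern(prob, c(1L, 3L), engine_config(n_starts = 25, seed = 7))
  expect_gte(s25$scalar_objective, s1$scalar_objective - 1e-10)
})

test_that("incremental search equals enumeration for a budget of one", {
  m <- generate_toy_model(4, branching = TRUE, seed = 6)
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
  prob <- make_problem(m, b, objective_spec("R4"), type = "primal")
  cfg <- engine_config(n_starts = 5, seed = 1)
  inc <- solve_incremental(prob, 1L, cfg)
  enum <- NULL
  for (p in enumerate_patterns(length(m$enzymes$id), 1))
    enum <- if (is.null(enum) ||
                solve_fixed_pattern(prob, p, cfg)$scalar_objective >
                enum$scalar_objective)
      solve_fixed_pattern(prob, p, cfg) else enum
  expect_identical(inc$modulated_ids, enum$modulated_ids)
  expect_equal(inc$scalar_objective, enum$scalar_objective, tolerance = 1e-8)
})

test_that("incremental search is bounded by, and usually equals, enumeration", {
  agree <- 0L; total <- 0L
  for (seed in 1:10) {
    m <- generate_toy_model(3, branching = TRUE, seed = seed)
    b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
    prob <- make_problem(m, b, objective_spec("R3"), type = "primal")
    cfg <- engine_config(n_starts = 4, seed = seed)
    inc <- solve_incremental(prob, 2L, cfg)
    best <- NULL
    for (p in enumerate_patterns(length(m$enzymes$id), 2)) {
      s <- solve_fixed_pattern(prob, p, cfg)
      if (is.null(best) || (s$feasible &&
                            s$scalar_objective > best$scalar_objective))
        best <- s
    }
    total <- total + 1L
    expect_lte(inc$scalar_objective, best$scalar_objective * (1 + 1e-6))
    if (abs(inc$scalar_objective - best$scalar_objective) <
        1e-4 * best$scalar_objective)
      agree <- agree + 1L
  }
  expect_gte(agree / total, 0.95)
})

test_that("the evolutionary mode returns a feasible, oracle-bounded solution", {
  m <- generate_toy_model(3, branching = TRUE, seed = 8)
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
  obj <- objective_spec("R3")
  ev <- solve_primal(m, b, obj, 2, engine_config(mode = "evolutionary",
                                                 n_starts = 5, seed = 2))
  en <- solve_primal(m, b, obj, 2, engine_config(n_starts = 5, seed = 2))
  expect_true(ev$feasible)
  expect_lte(ev$scalar_objective, en$scalar_objective * (1 + 1e-6))
})
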