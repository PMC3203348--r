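# Fuzzy resilience problem: dominance, degeneration to the primal
# ranking, memberships, over-estimation analysis, conservation variant.

test_that("resilience optima never exceed the primal optimum", {
  for (seed in c(2, 7)) {
    m <- generate_toy_model(3, branching = TRUE, seed = seed)
    b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
    obj <- objective_spec("R3")
    eng <- engine_config(n_starts = 5, seed = seed)
    ps <- solve_primal(m, b, obj, 2, eng)
    rs <- solve_resilience(m, b, obj, 2, fuzzy_config(), eng,
                           flux_ub = unname(ps$flux_ratios[[1]]))
    expect_lte(rs$flux_ratios[[1]], ps$flux_ratios[[1]] * (1 + 1e-6))
    expect_true(all(rs$memberships >= 0 & rs$memberships <= 1))
    expect_gte(rs$eta_D, 0)
  }
})

test_that("without resilience goals the fuzzy ranking matches the primal one", {
  m <- generate_toy_model(4, branching = TRUE, seed = 5)
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
  obj <- objective_spec("R4")
  eng <- engine_config(n_starts = 5, seed = 3)
  ps <- solve_primal(m, b, obj, 2, eng)
  fz <- fuzzy_config(sigma_X = "none", sigma_E = "none",
                     zeta_soft = c(50, 100),
                     viability_in_aggregation = FALSE)
  rs <- solve_resilience(m, b, obj, 2, fz, eng,
                         flux_ub = unname(ps$flux_ratios[[1]]) * 1.001)
  expect_identical(rs$modulated_ids, ps$modulated_ids)
  expect_equal(rs$flux_ratios[[1]], ps$flux_ratios[[1]], tolerance = 1e-3)
})

test_that("goal grades respond to the configured membership sets", {
  m <- yeast_model()
  b <- yeast_test_bounds()
  obj <- objective_spec("PYK", flux_ub = 2.45)
  eng <- engine_config(n_starts = 4, seed = 1)
  rs <- solve_resilience(m, b, obj, 1, fuzzy_config(), eng, flux_ub = 2.45)
  nms <- names(rs$memberships)
  expect_true(all(m$metabolites$id %in% nms))
  expect_true(all(m$enzymes$id %in% nms))
  expect_true(all(c("viability_x", "viability_e") %in% nms))
  rs2 <- solve_resilience(m, b, obj, 1,
                          fuzzy_config(sigma_X = "none",
                                       sigma_E = "unmodulated"),
                          eng, flux_ub = 2.45)
  expect_false(any(m$metabolites$id %in% names(rs2$memberships)))
  expect_false(any(rs2$modulated_ids %in% names(rs2$memberships)))
})

test_that("over-estimation tables compare fronts correctly", {
  f <- data.frame(epsilon = 1:3, ratio_R3 = c(1.5, 2, 2.5))
  attr(f, "targets") <- "R3"
  class(f) <- c("fmoop_front", class(f))
  oe <- overestimation_analysis(f, f)
  expect_equal(oe$overestimation_pct, rep(0, 3))
  expect_equal(oe$quotient, rep(1, 3))
  g <- f; g$epsilon <- 2:4
  expect_error(overestimation_analysis(f, g), "grids")
})

test_that("the conservation variant holds the pool relations exactly", {
  m <- ecoli_model()
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1),
                   gamma_x = c(0.2, 5), zeta_x = Inf, zeta_e = Inf)
  obj <- objective_spec("DAHPS")
  prob <- make_problem(m, b, obj, type = "soop", conservation = TRUE)
  s <- solve_fixed_pattern(prob, match("PK", m$enzymes$id),
                           engine_config(n_starts = 4, seed = 1))
  expect_true(s$feasible)
  co_ids <- m$metabolites$id[m$metabolites$co_metabolite]
  co_levels <- s$state$metabolite_levels[co_ids]
  expect_equal(unname(conservation_residuals(m, co_levels)), rep(0, 3),
               tolerance = 1e-10)
  # the optimizer actually uses the freedom: with conservation active the
  # objective can only improve relative to pinned co-metabolites
  s0 <- solve_fixed_pattern(make_problem(m, b, obj, type = "soop"),
                            match("PK", m$enzymes$id),
                            engine_config(n_starts = 4, seed = 1))
  expect_gte(s$scalar_objective, s0$scalar_objective - 1e-6)
})

test_that("fuzzy problems insist on resolved flux upper anchors", {
  m <- generate_toy_model(2, branching = FALSE, seed = 2)
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
  expect_error(make_problem(m, b, objective_spec("R2"), type = "fuzzy",
                            fuzzy = fuzzy_config()),
               "upper bounds")
})
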