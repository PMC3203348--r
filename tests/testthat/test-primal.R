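# Crisp primal problem: intervals, feasibility reports, scalarization,
# bound estimation, budget sweeps.

test_that("enzyme intervals follow the pattern and the bound factors", {
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(0.9, 1.1))
  p <- manipulation_pattern(c(1, 0, 0), epsilon = 2)
  expect_equal(enzyme_interval(p, 1, b, 1.0), c(0.2, 5.0))
  expect_equal(enzyme_interval(p, 2, b, 2.0), c(1.8, 2.2))
  b2 <- bounds_spec(gamma_e = c(0.8, 1.25), gamma_b = c(0.9, 1.1))
  expect_equal(enzyme_interval(p, 1, b2, 1.0), c(0.8, 1.25))
  expect_error(enzyme_interval(p, 9, b, 1.0), "out of range")
})

test_that("manipulation patterns enforce their invariants", {
  expect_error(manipulation_pattern(c(0, 0, 0)), "at least one")
  expect_error(manipulation_pattern(c(1, 1, 1), epsilon = 2), "epsilon")
  expect_error(manipulation_pattern(c(2, 0, 0)), "binary")
  p <- manipulation_pattern(c(1, 1, 0), epsilon = 3)
  expect_equal(sum(p$y), 2L)
})

test_that("feasibility reports isolate the violated constraint family", {
  m <- yeast_model()
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(0.9, 1.1),
                   gamma_x = c(0.2, 5), zeta_x = 2, zeta_e = 2)
  basal_state <- steady_state(m)
  # all-zero pattern: only the minimum-modulation constraint fails
  rep0 <- check_feasible(m, list(pattern = list(y = rep(0L, 8)),
                                 state = basal_state), b)
  expect_false(attr(rep0, "feasible"))
  bad <- rep0$constraint[!rep0$ok]
  expect_identical(bad, "min_modulation")
  # one modulated enzyme at basal: feasible throughout
  rep1 <- check_feasible(m, list(pattern = list(y = c(1L, rep(0L, 7))),
                                 state = basal_state), b, epsilon = 2)
  expect_true(attr(rep1, "feasible"))
  # inflate the metabolite total beyond the viability cap
  st2 <- basal_state
  st2$metabolite_levels <- basal_state$metabolite_levels * 3.1
  rep2 <- check_feasible(m, list(pattern = list(y = c(1L, rep(0L, 7))),
                                 state = st2), b)
  expect_true("viability_metabolite" %in% rep2$constraint[!rep2$ok])
})

test_that("the infinite-norm scalarization matches its closed form", {
  obj <- objective_spec("A", flux_lb = 1, flux_ub = 3)
  expect_equal(scalarize_infnorm(c(A = 3), obj), 0)
  expect_equal(scalarize_infnorm(c(A = 1), obj), 1)
  obj2 <- objective_spec(c("A", "B"), flux_lb = c(1, 1), flux_ub = c(3, 5))
  expect_equal(scalarize_infnorm(c(A = 2, B = 3), obj2), 0.5)
  expect_error(objective_spec("A", flux_lb = 2, flux_ub = 2), "exceed")
  bad <- objective_spec("A"); bad$flux_ub <- 1   # degenerate bounds
  expect_error(scalarize_infnorm(c(A = 2), bad), "degenerate")
})

test_that("upper-bound estimation coincides with the single-target optimum", {
  m <- generate_toy_model(3, branching = TRUE, seed = 3)
  b <- bounds_spec(gamma_e = c(0.5, 2), gamma_b = c(1, 1),
                   gamma_x = c(0.01, 100), zeta_x = Inf, zeta_e = Inf)
  obj <- objective_spec("R3")
  eng <- engine_config(n_starts = 5, seed = 1)
  ub <- estimate_flux_upper_bounds(m, b, obj, epsilon = 2, engine = eng)
  ps <- solve_primal(m, b, obj, 2, eng)
  expect_equal(unname(ub), unname(ps$flux_ratios[[1]]), tolerance = 1e-6)
})

test_that("a flux insensitive to the allowed modulations keeps bound one", {
  m <- generate_toy_model(2, branching = FALSE, seed = 1)
  b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
  # R0 = k E1 is zero order in the metabolites; with E1 excluded from the
  # candidates its flux cannot move
  ub <- estimate_flux_upper_bounds(m, b, objective_spec("R0"), epsilon = 2,
                                   engine = engine_config(n_starts = 3, seed = 1),
                                   candidates = c("E2", "E3"))
  expect_equal(unname(ub), 1, tolerance = 1e-6)
})

test_that("full-budget optimum of a monotone toy sits at the box corner", {
  m <- generate_toy_model(3, branching = FALSE, seed = 12)
  b <- bounds_spec(gamma_e = c(0.5, 2), gamma_b = c(1, 1),
                   gamma_x = c(0.01, 100), zeta_x = Inf, zeta_e = Inf)
  # flux through a simple chain equals the inflow k E1: the optimum puts
  # E1 at its upper bound and the ratio equals that bound
  s <- solve_primal(m, b, objective_spec("R3"), epsilon = 4,
                    engine_config(n_starts = 5, seed = 2))
  expect_equal(unname(s$flux_ratios[[1]]), 2, tolerance = 1e-5)
  expect_true(attr(check_feasible(m, s, b, epsilon = 4), "feasible"))
})

test_that("budget sweeps are monotone and their solutions re-validate", {
  for (seed in c(1, 9)) {
    m <- generate_toy_model(3, branching = TRUE, seed = seed)
    b <- bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1))
    eng <- engine_config(n_starts = 5, seed = seed)
    fr <- pareto_sweep(m, b, objective_spec("R3"), 1:5, eng)
    ratios <- fr$ratio_R3
    expect_true(all(diff(ratios) >= -1e-8))
    for (s in attr(fr, "solutions"))
      expect_true(attr(check_feasible(m, s, b), "feasible"))
    # the sweep front equals independent per-budget enumeration
    for (eps in c(1, 3)) {
      direct <- solve_primal(m, b, objective_spec("R3"), eps, eng)
      expect_equal(fr$ratio_R3[fr$epsilon == eps],
                   unname(direct$flux_ratios[[1]]), tolerance = 1e-6)
    }
  }
})
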