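# Model container, rate evaluation, steady states and file round trips.

test_that("yeast fixture reproduces its recorded basal state", {
  m <- yeast_model()
  expect_equal(nrow(m$metabolites), 5L)
  expect_equal(length(m$rates), 8L)
  xb <- setNames(m$metabolites$basal, m$metabolites$id)
  eb <- setNames(m$enzymes$basal, m$enzymes$id)
  v <- evaluate_rates(m, xb, eb)
  expect_equal(unname(v), unname(m$basal_fluxes[names(v)]), tolerance = 1e-8)
  expect_lt(max(abs(m$S %*% v)), 1e-8 * max(m$basal_fluxes))
})

test_that("ethanol flux responds to the fructose pool with its kinetic order", {
  m <- yeast_model()
  xb <- setNames(m$metabolites$basal, m$metabolites$id)
  eb <- setNames(m$enzymes$basal, m$enzymes$id)
  v0 <- evaluate_rates(m, xb, eb)
  x2 <- xb; x2["fdp"] <- 2 * xb["fdp"]
  v2 <- evaluate_rates(m, x2, eb)
  expect_equal(unname(v2["PYK"] / v0["PYK"]), 2^0.05, tolerance = 1e-10)
})

test_that("setting an enzyme activity to zero silences its reaction", {
  m <- yeast_model()
  xb <- setNames(m$metabolites$basal, m$metabolites$id)
  eb <- setNames(m$enzymes$basal, m$enzymes$id)
  eb["PFK"] <- 0
  v <- evaluate_rates(m, xb, eb)
  expect_identical(unname(v["PFK"]), 0)
  expect_gt(v["HXT"], 0)
})

test_that("power-law rates are log-linear and first order in their enzyme", {
  for (m in list(yeast_model(), generate_toy_model(4, TRUE, seed = 7))) {
    xb <- setNames(m$metabolites$basal, m$metabolites$id)
    eb <- setNames(m$enzymes$basal, m$enzymes$id)
    v0 <- evaluate_rates(m, xb, eb)
    set.seed(11)
    for (rep in 1:10) {
      f1 <- exp(runif(length(xb), -1, 1))
      f2 <- exp(runif(length(xb), -1, 1))
      vA <- evaluate_rates(m, xb * f1, eb)
      vB <- evaluate_rates(m, xb * f2, eb)
      vAB <- evaluate_rates(m, xb * f1 * f2, eb)
      # log v additive in log x contributions
      expect_equal(log(vAB / v0), log(vA / v0) + log(vB / v0),
                   tolerance = 1e-9)
    }
    k <- exp(runif(length(eb), -1, 1))
    vk <- evaluate_rates(m, xb, eb * k)
    enz_of <- match(vapply(m$rates, `[[`, "", "enzyme"), m$enzymes$id)
    expect_equal(unname(vk / v0), unname(k[enz_of]), tolerance = 1e-9)
  }
})

test_that("steady state at basal activities is the basal state", {
  for (m in list(yeast_model(), ecoli_model(), toy_mm())) {
    ss <- steady_state(m)
    xb <- setNames(m$metabolites$basal, m$metabolites$id)
    expect_equal(unname(ss$metabolite_levels), unname(xb), tolerance = 1e-6)
    expect_lt(ss$residual_norm, 1e-9)
  }
})

test_that("two-metabolite toy matches its closed-form steady state", {
  m <- toy_2met()
  ss <- steady_state(m, e = c(E1 = 1, E2 = 1, E3 = 1))
  expect_equal(unname(ss$metabolite_levels), c(1, 1), tolerance = 1e-8)
  ss2 <- steady_state(m, e = c(E1 = 2, E2 = 1, E3 = 1))
  expect_equal(unname(ss2$metabolite_levels), c(2, 2), tolerance = 1e-8)
  ss3 <- steady_state(m, e = c(E1 = 1.7, E2 = 0.4, E3 = 2.2))
  expect_equal(unname(ss3$metabolite_levels), c(1.7 / 0.4, 1.7 / 2.2),
               tolerance = 1e-8)
  # re-solving from a solution is a fixed point
  ss4 <- steady_state(m, e = c(E1 = 1.7, E2 = 0.4, E3 = 2.2),
                      x0 = ss3$metabolite_levels)
  expect_equal(ss4$metabolite_levels, ss3$metabolite_levels,
               tolerance = 1e-9)
})

test_that("general-expression rate laws solve through the same interface", {
  m <- toy_mm()
  # doubling the inflow forces v2 = 2 at steady state:
  # 2 x / (1 + x) = 2 has no finite solution, so use 1.5:
  ss <- steady_state(m, e = c(E1 = 1.5, E2 = 1, E3 = 1))
  x1 <- ss$metabolite_levels[["X1"]]
  expect_equal(2 * x1 / (1 + x1), 1.5, tolerance = 1e-7)
  expect_equal(ss$metabolite_levels[["X2"]], 1.5, tolerance = 1e-7)
})

test_that("E. coli fixture has the documented dimensions", {
  m <- ecoli_model()
  expect_equal(length(m$rates), 30L)
  expect_equal(sum(!m$metabolites$co_metabolite), 18L)
  expect_equal(sum(m$metabolites$co_metabolite), 7L)
  expect_false(is.null(m$conservation))
})

test_that("model files round-trip bit-identically", {
  m <- yeast_model()
  tf <- tempfile(fileext = ".json")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(m$metabolites, m2$metabolites)
  expect_identical(m$enzymes, m2$enzymes)
  expect_identical(m$S, m2$S)
  expect_identical(m$basal_fluxes, m2$basal_fluxes)
  expect_identical(lapply(m$rates, `[[`, "expression"),
                   lapply(m2$rates, `[[`, "expression"))
  expect_identical(lapply(m$rates, `[[`, "parameters"),
                   lapply(m2$rates, `[[`, "parameters"))
  unlink(tf)
})

test_that("malformed models are rejected with descriptive errors", {
  m <- toy_2met()
  # stoichiometry of the wrong shape
  bad_S <- m$S[, 1:2]
  expect_error(kinetic_model(m$metabolites, m$enzymes, m$rates, bad_S,
                             m$basal_fluxes), "dimension mismatch")
  # unknown identifier in a rate expression
  bad_rates <- m$rates
  bad_rates[[2]] <- rate_law("v2", "E2", "k * E2 * X9",
                             parameters = list(k = 1))
  expect_error(kinetic_model(m$metabolites, m$enzymes, bad_rates, m$S,
                             m$basal_fluxes), "unknown identifier")
  # grammar rejects function calls
  expect_error(
    kinetic_model(m$metabolites, m$enzymes,
                  list(m$rates[[1]], rate_law("v2", "E2", "exp(X1) * E2"),
                       m$rates[[3]]),
                  m$S, m$basal_fluxes),
    "grammar")
  # basal state that is not a steady state
  bad_flux <- m$basal_fluxes
  bad_flux["v2"] <- 2
  expect_error(kinetic_model(m$metabolites, m$enzymes, m$rates, m$S,
                             bad_flux), "basal")
})

test_that("conservation residuals vanish at basal and under uniform scaling", {
  m <- ecoli_model()
  co_ids <- m$metabolites$id[m$metabolites$co_metabolite]
  co_b <- setNames(m$metabolites$basal[m$metabolites$co_metabolite], co_ids)
  expect_equal(unname(conservation_residuals(m, co_b)), rep(0, 3))
  expect_equal(unname(conservation_residuals(m, co_b * 3.7)), rep(0, 3),
               tolerance = 1e-12)
  # raising atp with adp + amp compensating so the totals stay fixed
  shifted <- co_b
  shifted["atp"] <- co_b["atp"] + 0.2
  shifted["adp"] <- co_b["adp"] - 0.1
  shifted["amp"] <- co_b["amp"] - 0.1
  r <- conservation_residuals(m, shifted)
  ec_new <- (shifted[["atp"]] + 0.5 * shifted[["adp"]]) /
    (shifted[["atp"]] + shifted[["adp"]] + shifted[["amp"]])
  ec_old <- (co_b[["atp"]] + 0.5 * co_b[["adp"]]) /
    (co_b[["atp"]] + co_b[["adp"]] + co_b[["amp"]])
  expect_equal(unname(r["energy_charge"]), ec_new - ec_old, tolerance = 1e-12)
  expect_equal(unname(r[c("nadh_fraction", "nadph_fraction")]), c(0, 0))
  # missing id is a validation error
  expect_error(conservation_residuals(m, co_b[-1]), "missing")
})

test_that("stability diagnostic reports a finite spectral abscissa", {
  m <- yeast_model()
  ss <- steady_state(m)
  sa <- stability_diagnostic(m, ss)
  expect_true(is.finite(sa))
})
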