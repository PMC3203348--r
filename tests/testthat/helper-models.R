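# In-code fixtures and independent oracles used across the test files.

# Two-metabolite linear pathway with closed-form steady state:
# v1 = e1 (constant inflow), v2 = e2 x1, v3 = e3 x2, so
# x1* = e1 / e2 and x2* = e1 / e3.
toy_2met <- function() {
  mets <- data.frame(id = c("X1", "X2"), basal = 1, co_metabolite = FALSE)
  enz <- data.frame(id = c("E1", "E2", "E3"), basal = 1)
  rates <- list(
    rate_law("v1", "E1", "k * E1", parameters = list(k = 1)),
    rate_law("v2", "E2", "k * E2 * X1", parameters = list(k = 1)),
    rate_law("v3", "E3", "k * E3 * X2", parameters = list(k = 1)))
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("X1", "X2"), c("v1", "v2", "v3")))
  kinetic_model(mets, enz, rates, S,
                basal_fluxes = c(v1 = 1, v2 = 1, v3 = 1), name = "toy-2met")
}

# Small mixed model with a Michaelis-Menten step to exercise the
# general-expression path: v2 = Vmax x1 / (Km + x1) * E2.
toy_mm <- function() {
  mets <- data.frame(id = c("X1", "X2"), basal = 1, co_metabolite = FALSE)
  enz <- data.frame(id = c("E1", "E2", "E3"), basal = 1)
  rates <- list(
    rate_law("v1", "E1", "k * E1", parameters = list(k = 1)),
    rate_law("v2", "E2", "Vmax * X1 / (Km + X1) * E2",
             kind = "general_expression",
             parameters = list(Vmax = 2, Km = 1)),
    rate_law("v3", "E3", "k * E3 * X2", parameters = list(k = 1)))
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("X1", "X2"), c("v1", "v2", "v3")))
  kinetic_model(mets, enz, rates, S,
                basal_fluxes = c(v1 = 1, v2 = 1, v3 = 1), name = "toy-mm")
}

# Independent steady-state oracle for generated toy pathways: solves the
# chain sequentially in closed form, using uniroot at the branch node.
# Reads rate constants and kinetic orders from the rate parameters; does
# not touch the package's Newton solver.
oracle_toy_steady <- function(model, e) {
  rids <- vapply(model$rates, `[[`, "", "id")
  pars <- lapply(model$rates, `[[`, "parameters")
  names(pars) <- rids
  n <- nrow(model$metabolites)
  has_branch <- "Rbranch" %in% rids
  branch_at <- if (has_branch) {
    as.integer(sub("X", "", rownames(model$S)[model$S[, "Rbranch"] != 0]))
  } else 0L
  e <- stats::setNames(as.numeric(e), model$enzymes$id)
  x <- numeric(n)
  inflow <- pars$R0$k * e[["E1"]]
  v <- stats::setNames(numeric(length(rids)), rids)
  v["R0"] <- inflow
  for (i in seq_len(n)) {
    ri <- paste0("R", i)
    ki <- pars[[ri]]$k * e[[paste0("E", i + 1L)]]
    gi <- pars[[ri]]$g
    if (has_branch && i == branch_at) {
      kb <- pars$Rbranch$k * e[[paste0("E", n + 2L)]]
      gb <- pars$Rbranch$g
      f <- function(xx) ki * xx^gi + kb * xx^gb - inflow
      x[i] <- stats::uniroot(f, c(1e-12, 1e12), tol = 1e-14)$root
      v[ri] <- ki * x[i]^gi
      v["Rbranch"] <- kb * x[i]^gb
    } else {
      x[i] <- (inflow / ki)^(1 / gi)
      v[ri] <- inflow
    }
    inflow <- v[ri]
  }
  list(x = x, v = v)
}

# Dense grid oracle for the best flux ratio of the terminal main-chain
# reaction over a box of enzyme activity ratios (includes the endpoints,
# so corner optima are hit exactly).
oracle_grid_best <- function(model, free_ids, lo, hi, target,
                             n_grid = 13) {
  grid1 <- exp(seq(log(lo), log(hi), length.out = n_grid))
  grids <- rep(list(grid1), length(free_ids))
  combos <- as.matrix(expand.grid(grids))
  eb <- stats::setNames(model$enzymes$basal, model$enzymes$id)
  vb <- model$basal_fluxes[target]
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    e <- eb
    e[free_ids] <- eb[free_ids] * combos[r, ]
    sol <- oracle_toy_steady(model, e)
    ratio <- sol$v[[target]] / vb
    if (ratio > best) best <- ratio
  }
  unname(best)
}

yeast_test_bounds <- function(gamma_e = c(0.2, 5)) {
  bounds_spec(gamma_e = gamma_e, gamma_b = c(1, 1), gamma_x = c(0.2, 5),
              zeta_x = Inf, zeta_e = Inf)
}
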