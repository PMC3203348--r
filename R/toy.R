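# Synthetic pathway generator used by the property-style tests: a linear
# (optionally one-branch) chain with power-law kinetics whose basal state
# satisfies S v = 0 exactly by construction (basal fluxes are chosen first
# and rate constants back-solved), so no numerics enter the fixture itself.

#' Generate a synthetic toy pathway model
#'
#' Builds a linear pathway `X1 -> X2 -> ... -> Xn ->` fed by a constant
#' inflow, with one optional branch leaving the middle metabolite. Each
#' rate is a power law `k * e * x^g` with kinetic order `g` drawn uniformly
#' from \[0.1, 1\]; basal concentrations and activities are 1 and basal
#' fluxes are set to 1 (split across the branch), with rate constants
#' back-solved so the basal state is an exact steady state.
#'
#' @param n_metabolites number of dependent metabolites (>= 1).
#' @param branching logical; add a branch reaction from the middle
#'   metabolite.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a `kinetic_model`.
#' @export
generate_toy_model <- function(n_metabolites, branching = FALSE, seed = 0L) {
  if (n_metabolites < 1) stop("n_metabolites must be >= 1")
  orders <- with_local_seed(seed, stats::runif(n_metabolites, 0.1, 1.0))
  mets <- data.frame(id = paste0("X", seq_len(n_metabolites)),
                     basal = 1, co_metabolite = FALSE)
  n_rates <- n_metabolites + 1L + as.integer(branching)
  enz <- data.frame(id = paste0("E", seq_len(n_rates)), basal = 1,
                    display_name = paste0("E", seq_len(n_rates)))
  branch_at <- if (branching) max(1L, n_metabolites %/% 2L) else 0L
  split <- 0.5
  # basal fluxes: inflow 1; branch removes `split` at branch_at
  vb <- numeric(n_rates)
  vb[1] <- 1
  for (i in seq_len(n_metabolites)) {
    inflow <- vb[i]
    if (branching && i == branch_at) {
      vb[n_rates] <- split * inflow      # branch drain
      vb[i + 1L] <- inflow - vb[n_rates]
    } else {
      vb[i + 1L] <- inflow
    }
  }
  rates <- vector("list", n_rates)
  rates[[1]] <- rate_law("R0", "E1", "k * E1", kind = "power_law",
                         parameters = list(k = vb[1]))
  for (i in seq_len(n_metabolites)) {
    id <- paste0("R", i)
    eid <- paste0("E", i + 1L)
    rates[[i + 1L]] <- rate_law(
      id, eid, sprintf("k * %s * X%d ^ g", eid, i), kind = "power_law",
      parameters = list(k = vb[i + 1L], g = orders[i]))
  }
  if (branching) {
    eid <- paste0("E", n_rates)
    rates[[n_rates]] <- rate_law(
      "Rbranch", eid, sprintf("k * %s * X%d ^ g", eid, branch_at),
      kind = "power_law",
      parameters = list(k = vb[n_rates], g = 0.5 * (orders[branch_at] + 0.1)))
  }
  rate_ids <- vapply(rates, `[[`, "", "id")
  S <- matrix(0, n_metabolites, n_rates,
              dimnames = list(mets$id, rate_ids))
  for (i in seq_len(n_metabolites)) {
    S[i, i] <- S[i, i] + 1      # producing reaction R_{i-1}
    S[i, i + 1L] <- S[i, i + 1L] - 1
  }
  if (branching) S[branch_at, n_rates] <- -1
  kinetic_model(mets, enz, rates, S,
                basal_fluxes = stats::setNames(vb, rate_ids),
                name = sprintf("toy-%d%s-seed%d", n_metabolites,
                               if (branching) "b" else "", seed))
}

# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
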