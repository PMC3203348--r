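# Fuzzy (resilience) problem: the generalized fuzzy multi-objective
# formulation. Target fluxes carry fuzzy maximization goals; metabolites
# and enzymes carry fuzzy-equal goals anchored at the crisp bounds and
# peaked at the wild-type levels (the resilience phenomenon: a mutant
# settles close to its previous steady state); the two total-amount
# viability limits become fuzzy inequalities. All goals are aggregated by
# the delta-augmented min-max goal-attainment objective.

#' Solve the fuzzy resilience problem for a given enzyme budget
#'
#' Minimizes the augmented goal-attainment objective \eqn{\eta_D} over all
#' patterns with at most `epsilon` modulated enzymes. The flux membership
#' anchors run from `flux_lb` (grade 0) to the primal optimum at the same
#' budget (grade 1); pass `flux_ub` to override, otherwise it is estimated
#' by an internal primal run.
#'
#' @inheritParams solve_primal
#' @param fuzzy a [fuzzy_config()].
#' @param flux_ub optional per-target upper anchors for the flux
#'   memberships.
#' @return an `fmoop_solution` with membership grades and `eta_D`.
#' @export
solve_resilience <- function(model, bounds, objective, epsilon,
                             fuzzy = fuzzy_config(),
                             engine = engine_config(), flux_ub = NULL,
                             conservation = FALSE, keep_all = FALSE,
                             candidates = NULL) {
  objective <- resolve_flux_ub(model, bounds, objective, epsilon, engine,
                               conservation, flux_ub, candidates)
  prob <- make_problem(model, bounds, objective, type = "fuzzy",
                       fuzzy = fuzzy, conservation = conservation,
                       candidates = candidates)
  if (engine$mode == "incremental") {
    best <- solve_incremental(prob, epsilon, engine)
    sols <- list(best)
  } else {
    pats <- candidate_patterns(prob, epsilon, engine$max_patterns)
    sols <- enumerate_solve(prob, pats, engine)
    best <- pick_best(prob, sols)
  }
  if (is.null(best))
    stop("no feasible pattern for the resilience problem at epsilon = ", epsilon)
  best$epsilon <- epsilon
  best$objective <- objective
  if (keep_all) attr(best, "all_solutions") <- sols
  best
}

resolve_flux_ub <- function(model, bounds, objective, epsilon, engine,
                            conservation, flux_ub, candidates = NULL) {
  if (!is.null(flux_ub)) {
    objective$flux_ub <- rep_len(flux_ub, length(objective$target_flux_ids))
  } else if (anyNA(objective$flux_ub)) {
    if (length(objective$target_flux_ids) == 1L) {
      ps <- solve_primal(model, bounds, objective, epsilon, engine,
                         conservation, candidates = candidates)
      objective$flux_ub <- unname(ps$flux_ratios[1])
    } else {
      objective$flux_ub <- estimate_flux_upper_bounds(
        model, bounds, objective, epsilon, engine, conservation, candidates)
    }
  }
  if (any(objective$flux_ub <= objective$flux_lb))
    stop("flux upper anchors do not exceed the lower anchors")
  objective
}

# Per-budget fuzzy sweep. The flux-membership anchors are refreshed at
# each budget from the primal front; at each budget the exact-size
# patterns are enumerated and the previous best pattern is re-solved under
# the new anchors (with the bundled configurations any smaller pattern is
# dominated by a superset, so exact-size enumeration is exhaustive).
resilience_sweep <- function(model, bounds, objective, epsilon_range, engine,
                             fuzzy, conservation, flux_ub_front,
                             candidates = NULL) {
  if (is.null(fuzzy)) fuzzy <- fuzzy_config()
  if (is.null(flux_ub_front))
    flux_ub_front <- pareto_sweep(model, bounds, objective, epsilon_range,
                                  engine, "primal", conservation = conservation,
                                  candidates = candidates)
  front <- vector("list", length(epsilon_range))
  cloud <- list()
  prev_pattern <- NULL
  for (i in seq_along(epsilon_range)) {
    eps <- epsilon_range[i]
    obj_eps <- objective
    prow <- which(flux_ub_front$epsilon == eps)
    if (!length(prow))
      stop("primal front does not cover epsilon = ", eps)
    fub <- as.numeric(flux_ub_front[prow,
      paste0("ratio_", objective$target_flux_ids)])
    obj_eps$flux_ub <- pmax(fub, obj_eps$flux_lb + 1e-9)
    prob <- make_problem(model, bounds, obj_eps, type = "fuzzy",
                         fuzzy = fuzzy, conservation = conservation,
                         candidates = candidates)
    if (engine$mode == "incremental") {
      best <- solve_incremental(prob, eps, engine)
      sols <- list(best)
    } else {
      pats <- candidate_patterns(prob, eps, engine$max_patterns,
                                 exact_size = TRUE)
      if (!is.null(prev_pattern) && !any(vapply(pats, function(p)
        identical(p, prev_pattern), TRUE)))
        pats <- c(pats, list(prev_pattern))
      sols <- enumerate_solve(prob, pats, engine)
      best <- pick_best(prob, sols)
    }
    front[[i]] <- best
    cloud <- c(cloud, sols)
    if (!is.null(best)) prev_pattern <- which(best$pattern$y == 1L)
  }
  build_front(front, epsilon_range, objective, cloud, "resilience")
}

#' Over-estimation of productivity when resilience is ignored
#'
#' Compares a primal and a resilience front on a shared budget grid and
#' reports, per budget, the primal and resilience target ratios, the
#' resilience/primal quotient and the over-estimation percentage
#' \eqn{100 (f_{primal} - f_{resilience}) / f_{resilience}}.
#'
#' @param primal_front,resilience_front `fmoop_front` objects over the same
#'   budgets.
#' @param target which target ratio column to compare (default: first).
#' @return data.frame with columns `epsilon`, `primal`, `resilience`,
#'   `quotient`, `overestimation_pct`.
#' @export
overestimation_analysis <- function(primal_front, resilience_front,
                                    target = NULL) {
  if (!identical(primal_front$epsilon, resilience_front$epsilon))
    stop("fronts are on different budget grids")
  tgt <- target %||% attr(primal_front, "targets")[1]
  col <- paste0("ratio_", tgt)
  p <- primal_front[[col]]; r <- resilience_front[[col]]
  data.frame(epsilon = primal_front$epsilon,
             primal = p, resilience = r,
             quotient = r / p,
             overestimation_pct = 100 * (p - r) / r)
}
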