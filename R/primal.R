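# Crisp primal problem: choose which enzymes to modulate (binary pattern,
# at most epsilon) and their activity levels so that the target flux
# ratios are maximized over the feasible set defined by enzyme intervals,
# metabolite boxes, total-amount viability caps and the steady-state
# balances. Multiple targets are scalarized by the weighted infinite norm.

#' Weighted infinite-norm scalarization of target flux ratios
#'
#' Returns \eqn{\max_i (f^{UB}_i - f_i) / (f^{UB}_i - f^{LB}_i)}; minimizing
#' this maximizes the worst-off normalized target. Zero when every target
#' sits at its upper bound, one when all sit at their lower bounds.
#'
#' @param flux_ratios named or ordered vector of realized target ratios.
#' @param objective an [objective_spec()] with finite upper bounds.
#' @export
scalarize_infnorm <- function(flux_ratios, objective) {
  f <- if (!is.null(names(flux_ratios)))
    flux_ratios[objective$target_flux_ids] else flux_ratios
  ub <- objective$flux_ub; lb <- objective$flux_lb
  if (anyNA(ub)) stop("flux upper bounds are unset; estimate them first")
  if (any(ub - lb <= 0)) stop("degenerate scalarization bounds (flux_ub == flux_lb)")
  max((ub - f) / (ub - lb))
}

#' Check a solution against every constraint family
#'
#' Reports pass/fail for: enzyme intervals implied by the pattern, the
#' at-least-one-modulation requirement, the epsilon budget, metabolite
#' boxes, the two crisp viability caps, and the steady-state residual.
#'
#' @param model a `kinetic_model`.
#' @param solution an `fmoop_solution` (or any list with `pattern` and
#'   `state` fields).
#' @param bounds a [bounds_spec()].
#' @param epsilon optional budget to check the pattern against.
#' @param tol relative tolerance.
#' @return data.frame with columns `constraint`, `ok`, `detail`; attribute
#'   `feasible` gives the conjunction.
#' @export
check_feasible <- function(model, solution, bounds, epsilon = NULL,
                           tol = 1e-6) {
  cm <- model$compiled
  y <- solution$pattern$y
  st <- solution$state
  rows <- list()
  add <- function(name, ok, detail)
    rows[[length(rows) + 1L]] <<- data.frame(constraint = name, ok = ok,
                                             detail = detail)
  if (is.null(st)) {
    add("state", FALSE, "solution carries no steady state")
  } else {
    e <- st$enzyme_levels; x <- st$metabolite_levels
    lo <- ifelse(y == 1L, bounds$gamma_e[1], bounds$gamma_b[1]) * cm$eb
    hi <- ifelse(y == 1L, bounds$gamma_e[2], bounds$gamma_b[2]) * cm$eb
    bad <- which(e < lo * (1 - tol) | e > hi * (1 + tol))
    add("enzyme_bounds", length(bad) == 0L,
        if (length(bad)) paste("violated for", paste(names(cm$eb)[bad], collapse = ", "))
        else "all activities inside their intervals")
    xd <- x[cm$dep]; xbd <- cm$xb[cm$dep]
    badx <- which(xd < bounds$gamma_x[1] * xbd * (1 - tol) |
                    xd > bounds$gamma_x[2] * xbd * (1 + tol))
    add("metabolite_bounds", length(badx) == 0L,
        if (length(badx)) paste("violated for", paste(names(xbd)[badx], collapse = ", "))
        else "all concentrations inside their boxes")
    tx <- sum(xd) / sum(xbd); te <- sum(e) / sum(cm$eb)
    add("viability_metabolite",
        !is.finite(bounds$zeta_x) || tx <= bounds$zeta_x * (1 + tol),
        sprintf("total ratio %.4f vs cap %s", tx, format(bounds$zeta_x)))
    add("viability_enzyme",
        !is.finite(bounds$zeta_e) || te <= bounds$zeta_e * (1 + tol),
        sprintf("total ratio %.4f vs cap %s", te, format(bounds$zeta_e)))
    add("steady_state", st$residual_norm <= 1e-6,
        sprintf("scaled residual %.3g", st$residual_norm))
  }
  add("min_modulation", sum(y) >= 1L, sprintf("%d enzyme(s) modulated", sum(y)))
  if (!is.null(epsilon))
    add("epsilon_budget", sum(y) <= epsilon,
        sprintf("%d modulated vs budget %d", sum(y), epsilon))
  out <- do.call(rbind, rows)
  attr(out, "feasible") <- all(out$ok)
  class(out) <- c("feasibility_report", class(out))
  out
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("Feasibility:", if (attr(x, "feasible")) "PASS" else "FAIL", "\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-22s %s\n", if (x$ok[i]) "ok" else "XX",
                x$constraint[i], x$detail[i]))
  invisible(x)
}

# Solve every pattern in a list, deterministically; returns solutions.
enumerate_solve <- function(prob, patterns, config) {
  lapply(patterns, function(mod) solve_fixed_pattern(prob, mod, config))
}

pick_best <- function(prob, sols) {
  best <- NULL
  for (s in sols) if (solution_better(prob, s, best)) best <- s
  best
}

#' Estimate per-target flux-ratio upper bounds by single-objective solves
#'
#' For each target flux, maximizes that ratio alone over the same feasible
#' set (including the epsilon budget) and returns the optimum; these bounds
#' normalize the infinite-norm scalarization and anchor the fuzzy
#' maximization memberships.
#'
#' @param model a `kinetic_model`.
#' @param bounds a [bounds_spec()].
#' @param objective an [objective_spec()].
#' @param epsilon budget used for the bound runs (the library default is
#'   the same epsilon as the consuming run; pass `epsilon = m` for global
#'   bounds).
#' @param engine an [engine_config()].
#' @param conservation logical; use the co-metabolite conservation variant.
#' @param candidates enzymes eligible for modulation (ids or indices;
#'   default all). Steps that are operating conditions rather than genetic
#'   targets can be excluded this way.
#' @return named numeric vector of upper-bound ratios.
#' @export
estimate_flux_upper_bounds <- function(model, bounds, objective, epsilon,
                                       engine = engine_config(),
                                       conservation = FALSE,
                                       candidates = NULL) {
  vapply(objective$target_flux_ids, function(tid) {
    prob <- make_problem(model, bounds, objective_spec(tid), type = "soop",
                         conservation = conservation,
                         candidates = candidates)
    sol <- if (engine$mode == "incremental")
      solve_incremental(prob, epsilon, engine)
    else pick_best(prob, enumerate_solve(
      prob, candidate_patterns(prob, epsilon, engine$max_patterns), engine))
    if (is.null(sol) || sol$failed || !sol$feasible)
      stop("upper-bound estimation failed for target '", tid, "'")
    unname(sol$scalar_objective)
  }, numeric(1))
}

#' Solve the crisp primal problem for a given enzyme budget
#'
#' Finds the best feasible pattern with between 1 and `epsilon` modulated
#' enzymes together with optimal activity levels. With a single target the
#' objective is the raw flux ratio; with several targets the weighted
#' infinite norm is minimized, with upper bounds estimated by
#' single-objective runs when not supplied. Ties are broken toward fewer
#' modulated enzymes, then the lexicographically smallest index set.
#'
#' @inheritParams estimate_flux_upper_bounds
#' @param epsilon allowed number of modulated enzymes.
#' @param keep_all also return the per-pattern solutions (the feasible
#'   point cloud).
#' @return an `fmoop_solution`; with `keep_all = TRUE`, attribute
#'   `all_solutions` holds the full enumeration.
#' @export
solve_primal <- function(model, bounds, objective, epsilon,
                         engine = engine_config(), conservation = FALSE,
                         keep_all = FALSE, candidates = NULL) {
  multi <- length(objective$target_flux_ids) > 1L
  if (multi && anyNA(objective$flux_ub)) {
    fub <- estimate_flux_upper_bounds(model, bounds, objective, epsilon,
                                      engine, conservation, candidates)
    objective$flux_ub <- ifelse(is.na(objective$flux_ub), fub,
                                objective$flux_ub)
  }
  prob <- make_problem(model, bounds, objective, type = "primal",
                       conservation = conservation, candidates = candidates)
  if (engine$mode == "incremental") {
    best <- solve_incremental(prob, epsilon, engine)
    sols <- list(best)
  } else if (engine$mode == "evolutionary") {
    best <- solve_evolutionary(prob, epsilon, engine)
    sols <- list(best)
  } else {
    pats <- candidate_patterns(prob, epsilon, engine$max_patterns)
    sols <- enumerate_solve(prob, pats, engine)
    best <- pick_best(prob, sols)
  }
  if (is.null(best)) {
    reasons <- vapply(sols, function(s)
      if (s$failed) s$reason %||% "failed" else "infeasible", "")
    stop("no feasible pattern found; per-pattern outcomes: ",
         paste(unique(reasons), collapse = "; "))
  }
  best$epsilon <- epsilon
  best$objective <- prob$objective
  if (keep_all) attr(best, "all_solutions") <- sols
  best
}

#' Trace the Pareto front over the enzyme budget
#'
#' Solves the primal (or fuzzy resilience) problem for every budget in
#' `epsilon_range` and reports the per-budget optimum; for single-target
#' primal problems each pattern is solved once and fronts are assembled by
#' cumulative best, and the full per-pattern point cloud is retained.
#'
#' @inheritParams solve_primal
#' @param epsilon_range integer vector of budgets (e.g. `1:8`).
#' @param problem `"primal"` or `"resilience"`.
#' @param fuzzy a [fuzzy_config()] (resilience only).
#' @param flux_ub_front optional precomputed primal front used to anchor
#'   the fuzzy flux memberships; when absent it is computed internally.
#' @return an `fmoop_front`: data.frame of per-budget rows with the
#'   underlying solutions and point cloud as attributes.
#' @export
pareto_sweep <- function(model, bounds, objective, epsilon_range,
                         engine = engine_config(), problem = "primal",
                         fuzzy = NULL, conservation = FALSE,
                         flux_ub_front = NULL, candidates = NULL) {
  epsilon_range <- sort(unique(as.integer(epsilon_range)))
  if (problem == "resilience")
    return(resilience_sweep(model, bounds, objective, epsilon_range, engine,
                            fuzzy, conservation, flux_ub_front, candidates))
  multi <- length(objective$target_flux_ids) > 1L
  if (!multi && engine$mode == "enumerate") {
    prob <- make_problem(model, bounds, objective, type = "primal",
                         conservation = conservation, candidates = candidates)
    pats <- candidate_patterns(prob, max(epsilon_range), engine$max_patterns)
    sols <- enumerate_solve(prob, pats, engine)
    sizes <- vapply(sols, function(s) sum(s$pattern$y), 0L)
    front <- lapply(epsilon_range, function(eps)
      pick_best(prob, sols[sizes <= eps]))
    cloud <- sols
  } else {
    front <- lapply(epsilon_range, function(eps)
      solve_primal(model, bounds, objective, eps, engine, conservation,
                   candidates = candidates))
    cloud <- NULL
  }
  build_front(front, epsilon_range, objective, cloud, "primal")
}

build_front <- function(front, epsilon_range, objective, cloud, type) {
  rows <- lapply(seq_along(epsilon_range), function(i) {
    s <- front[[i]]
    if (is.null(s)) return(NULL)
    fr <- as.list(s$flux_ratios)
    names(fr) <- paste0("ratio_", names(s$flux_ratios))
    cbind(data.frame(epsilon = epsilon_range[i]), as.data.frame(fr),
          data.frame(objective = s$scalar_objective,
                     eta_D = s$eta_D %||% NA_real_,
                     modulated = paste(s$modulated, collapse = ", "),
                     feasible = s$feasible))
  })
  tab <- do.call(rbind, rows)
  structure(tab, solutions = front, cloud = cloud, problem = type,
            targets = objective$target_flux_ids,
            class = c("fmoop_front", class(tab)))
}
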