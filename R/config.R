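# Specification objects for the optimization problems: bound factors,
# manipulation patterns, objective targets, fuzzy settings, engine settings.

#' Bound and restriction factors defining the feasible set
#'
#' Dimensionless factors applied to basal values. Modulated ("significant")
#' enzymes may move within `gamma_e`, un-modulated enzymes only within the
#' narrower `gamma_b`; metabolites are boxed by `gamma_x`; `zeta_x` and
#' `zeta_e` cap the total metabolite and enzyme amounts relative to their
#' basal totals (crisp cell-viability limits; `Inf` disables them).
#'
#' @param gamma_e length-2 `c(lower, upper)` for modulated enzymes
#'   (lower < 1 < upper).
#' @param gamma_b length-2 factors for un-modulated enzymes; must satisfy
#'   `gamma_e[1] <= gamma_b[1] <= 1 <= gamma_b[2] <= gamma_e[2]`.
#' @param gamma_x length-2 factors bounding each metabolite.
#' @param zeta_x,zeta_e crisp viability factors (>= 1, possibly `Inf`).
#' @export
bounds_spec <- function(gamma_e = c(0.2, 5), gamma_b = c(0.9, 1.1),
                        gamma_x = c(0.2, 5), zeta_x = 2, zeta_e = 2) {
  stopifnot(length(gamma_e) == 2, length(gamma_b) == 2, length(gamma_x) == 2)
  if (!(gamma_e[1] < 1 && gamma_e[2] > 1))
    stop("gamma_e must straddle 1")
  if (!(gamma_e[1] <= gamma_b[1] && gamma_b[1] <= 1 &&
        1 <= gamma_b[2] && gamma_b[2] <= gamma_e[2]))
    stop("gamma_b must lie within gamma_e and contain 1")
  if (!(gamma_x[1] < gamma_x[2]) || gamma_x[1] <= 0)
    stop("gamma_x must be positive and ordered")
  if (zeta_x < 1 || zeta_e < 1) stop("zeta factors must be >= 1")
  structure(list(gamma_e = as.numeric(gamma_e), gamma_b = as.numeric(gamma_b),
                 gamma_x = as.numeric(gamma_x),
                 zeta_x = zeta_x, zeta_e = zeta_e),
            class = "bounds_spec")
}

#' Binary manipulation pattern
#'
#' @param y binary (0/1) vector over the model's enzymes: 1 marks a
#'   modulated enzyme.
#' @param epsilon allowed number of modulated enzymes; `sum(y)` must lie in
#'   `[1, epsilon]`.
#' @export
manipulation_pattern <- function(y, epsilon = sum(y)) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary")
  if (sum(y) < 1L) stop("at least one enzyme must be modulated")
  if (sum(y) > epsilon) stop("pattern modulates more enzymes than epsilon allows")
  structure(list(y = y, epsilon = as.integer(epsilon)),
            class = "manipulation_pattern")
}

#' Target fluxes and their scalarization bounds
#'
#' @param target_flux_ids rate ids whose basal-relative ratios are to be
#'   maximized.
#' @param flux_lb per-target lower bounds on the flux ratio (default 1: the
#'   manipulated flux should at least reach its basal value).
#' @param flux_ub per-target upper bounds; `NA` means "estimate by a
#'   single-objective solve" (see [estimate_flux_upper_bounds()]).
#' @export
objective_spec <- function(target_flux_ids, flux_lb = 1, flux_ub = NA_real_) {
  n <- length(target_flux_ids)
  flux_lb <- rep_len(flux_lb, n); flux_ub <- rep_len(flux_ub, n)
  if (any(!is.na(flux_ub) & flux_ub <= flux_lb))
    stop("flux_ub must exceed flux_lb for every target")
  structure(list(target_flux_ids = target_flux_ids,
                 flux_lb = flux_lb, flux_ub = flux_ub),
            class = "objective_spec")
}

#' Fuzzy problem configuration
#'
#' Settings for the goal-attainment formulation: which fluxes carry fuzzy
#' maximization goals, which metabolites and enzymes carry fuzzy-equal
#' (resilience) goals, the soft viability interval factors, the membership
#' shape, the ideal grades and the augmentation weight.
#'
#' @param sigma_O target flux ids (defaults to the objective's targets).
#' @param sigma_X `"all"`, `"none"`, or metabolite ids under fuzzy-equal
#'   goals (anchors at the crisp metabolite bounds).
#' @param sigma_E `"all"`, `"unmodulated"`, `"none"`, or enzyme ids under
#'   fuzzy-equal goals (anchors at the significant enzyme bounds).
#' @param zeta_soft length-2 `c(lower, upper)` soft viability factors
#'   applied to both totals; a solution whose total exceeds the upper
#'   anchor is infeasible.
#' @param delta augmentation weight in `[1e-5, 1e-3]`.
#' @param ideal_goals ideal membership grade per goal (default 1).
#' @param shape membership shape: `"linear"` (default), `"exponential"`,
#'   `"hyperbolic"`, `"inverse"` or `"piecewise_linear"`.
#' @param viability_in_aggregation include the two viability memberships in
#'   the aggregated objective (default TRUE).
#' @param enzyme_anchor_gamma optional `c(lower, upper)` fold-range
#'   anchoring the fuzzy-equal enzyme goals. By default the goals anchor at
#'   the significant enzyme bounds `gamma_e`; fixing this to a reference
#'   physiological range keeps the resilience scale constant when the
#'   allowed perturbation region is varied.
#' @export
fuzzy_config <- function(sigma_O = NULL, sigma_X = "all", sigma_E = "all",
                         zeta_soft = c(1.6, 2.0), delta = 1e-4,
                         ideal_goals = 1, shape = "linear",
                         viability_in_aggregation = TRUE,
                         enzyme_anchor_gamma = NULL) {
  if (delta < 1e-5 || delta > 1e-3)
    stop("delta must lie within [1e-5, 1e-3]")
  if (!(zeta_soft[1] < zeta_soft[2]))
    stop("soft viability factors must be ordered")
  shape <- match.arg(shape, c("linear", "exponential", "hyperbolic",
                              "inverse", "piecewise_linear"))
  if (!is.null(enzyme_anchor_gamma) &&
      !(enzyme_anchor_gamma[1] < 1 && enzyme_anchor_gamma[2] > 1))
    stop("enzyme_anchor_gamma must straddle 1")
  structure(list(sigma_O = sigma_O, sigma_X = sigma_X, sigma_E = sigma_E,
                 zeta_soft = as.numeric(zeta_soft), delta = delta,
                 ideal_goals = ideal_goals, shape = shape,
                 viability_in_aggregation = isTRUE(viability_in_aggregation),
                 enzyme_anchor_gamma = enzyme_anchor_gamma),
            class = "fuzzy_config")
}

#' Engine configuration
#'
#' @param mode `"enumerate"` (exact over all patterns), `"incremental"`
#'   (greedy growth plus swap local search) or `"evolutionary"`.
#' @param n_starts multistart count for each fixed-pattern solve (the basal
#'   start is always included first).
#' @param seed integer seed; identical configurations yield identical
#'   results.
#' @param nlp_tolerance feasibility tolerance used when post-checking
#'   solutions.
#' @param max_patterns refuse enumerations larger than this.
#' @param swap_depth local-search exchanges in incremental mode.
#' @export
engine_config <- function(mode = c("enumerate", "incremental", "evolutionary"),
                          n_starts = 25, seed = 1L, nlp_tolerance = 1e-6,
                          max_patterns = 1e5, swap_depth = 2L) {
  mode <- match.arg(mode)
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(mode = mode, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), nlp_tolerance = nlp_tolerance,
                 max_patterns = max_patterns, swap_depth = as.integer(swap_depth)),
            class = "engine_config")
}

#' Enzyme activity interval implied by a pattern
#'
#' Returns the feasible activity interval for one enzyme: the wide
#' significant interval if it is modulated, the narrow perturbation band
#' otherwise.
#'
#' @param pattern a [manipulation_pattern()].
#' @param enzyme_index index into the pattern.
#' @param bounds a [bounds_spec()].
#' @param basal the enzyme's basal activity.
#' @export
enzyme_interval <- function(pattern, enzyme_index, bounds, basal) {
  if (enzyme_index < 1 || enzyme_index > length(pattern$y))
    stop("enzyme_index out of range")
  g <- if (pattern$y[enzyme_index] == 1L) bounds$gamma_e else bounds$gamma_b
  g * basal
}
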