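# End-to-end case studies: ethanol production in the yeast fermentation
# network and simultaneous amino-acid precursor maximization in the
# E. coli central-carbon network, each as primal + resilience runs over a
# range of enzyme budgets, with over-estimation analysis.

#' Configuration for the yeast ethanol study
#'
#' Defaults reproduce the study conditions: 5-fold bounds on modulated
#' enzymes and on every metabolite, un-modulated enzymes held at basal,
#' crisp viability disabled for the primal problem, soft viability factors
#' (1.6, 2.0), linear memberships, ideal grades 1 and delta 1e-4.
#'
#' @param epsilon_range enzyme budgets to sweep.
#' @param n_starts multistart count for the primal enumeration.
#' @param resilience_starts multistart count for the fuzzy enumeration.
#' @param overestimation_starts multistart count for the additional
#'   perturbation-region sweeps.
#' @param factor_pairs list of `c(lower, upper)` enzyme perturbation
#'   regions for the over-estimation analysis (widest first).
#' @param seed engine seed.
#' @export
yeast_study_config <- function(epsilon_range = 1:8, n_starts = 25,
                               resilience_starts = 15,
                               overestimation_starts = 5,
                               factor_pairs = list(c(0.2, 5), c(0.4, 2.5),
                                                   c(0.8, 1.25)),
                               seed = 1L) {
  list(target = "PYK",
       epsilon_range = epsilon_range,
       bounds = bounds_spec(gamma_e = factor_pairs[[1]], gamma_b = c(1, 1),
                            gamma_x = c(0.2, 5), zeta_x = Inf, zeta_e = Inf),
       fuzzy = fuzzy_config(sigma_X = "all", sigma_E = "all",
                            zeta_soft = c(1.6, 2.0), delta = 1e-4),
       factor_pairs = factor_pairs,
       n_starts = n_starts, resilience_starts = resilience_starts,
       overestimation_starts = overestimation_starts, seed = seed)
}

#' Run the yeast ethanol production study
#'
#' Sweeps the primal and resilience problems over the enzyme budget,
#' solves the fixed-pattern (HXT, PFK) resilience NLP for comparison with
#' the optimal (HXT, TDH) pair, counts the enzyme pairs whose primal
#' optimum exceeds a 2-fold ethanol flux ratio, and quantifies the
#' over-estimation of productivity across perturbation-region widths.
#'
#' @param config from [yeast_study_config()].
#' @param model the yeast fixture (or a compatible model).
#' @param include_overestimation run the additional perturbation-region
#'   sweeps (the widest pair reuses the main fronts).
#' @return an `fmoop_study`.
#' @export
run_yeast_study <- function(config = yeast_study_config(),
                            model = yeast_model(),
                            include_overestimation = TRUE) {
  objective <- objective_spec(config$target)
  eng <- engine_config(n_starts = config$n_starts, seed = config$seed)
  eng_fz <- engine_config(n_starts = config$resilience_starts,
                          seed = config$seed)
  primal <- pareto_sweep(model, config$bounds, objective,
                         config$epsilon_range, eng)
  resilience <- pareto_sweep(model, config$bounds, objective,
                             config$epsilon_range, eng_fz,
                             problem = "resilience", fuzzy = config$fuzzy,
                             flux_ub_front = primal)
  # fixed-pattern NLP: resilience problem with modulation pinned to HXT+PFK
  fixed <- NULL
  ids <- model$enzymes$id
  if (all(c("HXT", "PFK") %in% ids) && 2 %in% primal$epsilon) {
    fub <- primal[primal$epsilon == 2, paste0("ratio_", config$target)]
    prob <- make_problem(model, config$bounds,
                         objective_spec(config$target, flux_ub = fub),
                         type = "fuzzy", fuzzy = config$fuzzy)
    fixed <- solve_fixed_pattern(prob, match(c("HXT", "PFK"), ids), eng_fz)
  }
  # census: enumerated pairs beating a 2-fold ethanol ratio
  cloud <- attr(primal, "cloud")
  census <- NULL
  if (!is.null(cloud)) {
    pairs <- Filter(function(s) sum(s$pattern$y) == 2L && !s$failed &&
                      s$feasible, cloud)
    ratios <- vapply(pairs, function(s) s$flux_ratios[[config$target]], 1)
    census <- list(n_pairs = length(pairs), n_above_2 = sum(ratios > 2.0),
                   ratios = sort(ratios, decreasing = TRUE))
  }
  over <- NULL
  if (include_overestimation) {
    over <- vector("list", length(config$factor_pairs))
    names(over) <- vapply(config$factor_pairs, function(p)
      sprintf("%g-%g", p[1], p[2]), "")
    over[[1]] <- overestimation_analysis(primal, resilience)
    eng_ov <- engine_config(n_starts = config$overestimation_starts,
                            seed = config$seed)
    fz_ref <- config$fuzzy
    fz_ref$enzyme_anchor_gamma <- config$factor_pairs[[1]]
    for (i in seq_along(config$factor_pairs)[-1]) {
      b_i <- config$bounds
      b_i$gamma_e <- config$factor_pairs[[i]]
      p_i <- pareto_sweep(model, b_i, objective, config$epsilon_range, eng_ov)
      r_i <- pareto_sweep(model, b_i, objective, config$epsilon_range, eng_ov,
                          problem = "resilience", fuzzy = fz_ref,
                          flux_ub_front = p_i)
      over[[i]] <- overestimation_analysis(p_i, r_i)
    }
  }
  structure(list(name = "yeast-ethanol",
                 primal_front = primal, resilience_front = resilience,
                 fixed_pattern_nlp = fixed, census = census,
                 overestimation = over, config = config),
            class = "fmoop_study")
}

#' Configuration for the E. coli amino-acid precursor study
#'
#' Tri-objective maximization of the PEPC, SERS and DAHPS flux ratios.
#' Enumeration is used for budgets up to `enumerate_up_to`; larger budgets
#' use the greedy incremental engine (justified by the nesting of optimal
#' enzyme sets across budgets). Single-objective bound runs use the
#' incremental engine throughout.
#'
#' @inheritParams yeast_study_config
#' @param conservation use the co-metabolite conservation variant.
#' @param enumerate_up_to largest budget solved by full enumeration.
#' @param excluded_enzymes enzymes never modulated (the glucose supply
#'   step is an operating condition, not a genetic target).
#' @export
ecoli_study_config <- function(epsilon_range = 1:5, n_starts = 8,
                               enumerate_up_to = 2L, conservation = FALSE,
                               excluded_enzymes = "GLCSUP", seed = 1L) {
  list(targets = c("PEPC", "SERS", "DAHPS"),
       excluded_enzymes = excluded_enzymes,
       epsilon_range = epsilon_range,
       bounds = bounds_spec(gamma_e = c(0.2, 5), gamma_b = c(1, 1),
                            gamma_x = c(0.2, 5), zeta_x = Inf, zeta_e = Inf),
       fuzzy = fuzzy_config(sigma_X = "all", sigma_E = "all",
                            zeta_soft = c(1.6, 2.0), delta = 1e-4),
       n_starts = n_starts, enumerate_up_to = as.integer(enumerate_up_to),
       conservation = conservation, seed = seed)
}

#' Run the E. coli multi-synthesis study
#'
#' For each budget: estimates per-target flux-ratio upper bounds by
#' single-objective runs, solves the tri-objective primal problem
#' (weighted infinite norm) and the fuzzy resilience problem, and tabulates
#' ratios, modulated enzymes and objective values.
#'
#' @param config from [ecoli_study_config()].
#' @param model the E. coli fixture (or a compatible model).
#' @return an `fmoop_study`.
#' @export
run_ecoli_study <- function(config = ecoli_study_config(),
                            model = ecoli_model()) {
  objective <- objective_spec(config$targets)
  cand <- setdiff(model$enzymes$id, config$excluded_enzymes)
  primal_sols <- list(); res_sols <- list()
  for (i in seq_along(config$epsilon_range)) {
    eps <- config$epsilon_range[i]
    mode <- if (eps <= config$enumerate_up_to) "enumerate" else "incremental"
    eng <- engine_config(mode = mode, n_starts = config$n_starts,
                         seed = config$seed)
    eng_soop <- engine_config(mode = if (eps == 1) "enumerate" else
      "incremental", n_starts = config$n_starts, seed = config$seed)
    fub <- estimate_flux_upper_bounds(model, config$bounds, objective, eps,
                                      eng_soop, config$conservation, cand)
    obj_eps <- objective
    obj_eps$flux_ub <- fub
    primal_sols[[i]] <- solve_primal(model, config$bounds, obj_eps, eps, eng,
                                     config$conservation, candidates = cand)
    res_sols[[i]] <- solve_resilience(model, config$bounds, obj_eps, eps,
                                      config$fuzzy, eng,
                                      flux_ub = fub,
                                      conservation = config$conservation,
                                      candidates = cand)
  }
  primal <- build_front(primal_sols, config$epsilon_range, objective, NULL,
                        "primal")
  resilience <- build_front(res_sols, config$epsilon_range, objective, NULL,
                            "resilience")
  structure(list(name = "ecoli-amino-acids",
                 primal_front = primal, resilience_front = resilience,
                 fixed_pattern_nlp = NULL, census = NULL,
                 overestimation = NULL, config = config),
            class = "fmoop_study")
}

#' @export
print.fmoop_study <- function(x, ...) {
  cat("Study:", x$name, "\n\n== Primal front ==\n")
  print(x$primal_front)
  cat("\n== Resilience front ==\n")
  print(x$resilience_front)
  if (!is.null(x$fixed_pattern_nlp)) {
    cat("\n== Fixed-pattern resilience NLP ==\n")
    print(x$fixed_pattern_nlp)
  }
  if (!is.null(x$census))
    cat(sprintf("\nPair census: %d of %d enzyme pairs exceed a 2-fold ratio\n",
                x$census$n_above_2, x$census$n_pairs))
  if (!is.null(x$overestimation)) {
    cat("\n== Over-estimation vs perturbation region ==\n")
    for (nm in names(x$overestimation)) {
      cat(" region", nm, ":\n")
      print(x$overestimation[[nm]], digits = 4, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Write study tables and a machine-readable run log
#'
#' Emits one TSV per front (budget, per-target flux ratios, modulated
#' enzymes, objective value), an over-estimation TSV when available, and a
#' JSON run log with the resolved configuration.
#'
#' @param study an `fmoop_study`.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wr(as.data.frame(study$primal_front), "primal_front.tsv")
  wr(as.data.frame(study$resilience_front), "resilience_front.tsv")
  if (!is.null(study$overestimation))
    for (nm in names(study$overestimation))
      wr(study$overestimation[[nm]], sprintf("overestimation_%s.tsv", nm))
  cfg <- study$config
  cfg_json <- list(name = study$name, config = cfg,
                   generated = "enzopt study report")
  jsonlite::write_json(cfg_json, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
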