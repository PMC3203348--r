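# Kinetic model container: metabolites, enzymes, rate laws, stoichiometry.
# Rate laws are either power laws (products of power terms, log-linear in
# log-concentrations) or general expressions; both are parsed from a small
# arithmetic grammar and validated against the model's symbol table.

#' Construct a kinetic metabolic model
#'
#' A kinetic model couples a stoichiometric matrix \eqn{S} with rate laws
#' \eqn{v(x, e; \theta)} so that the metabolite dynamics are
#' \eqn{dx/dt = S v(x, e; \theta)}. The recorded basal state (concentrations,
#' enzyme activities, fluxes) must itself be a steady state: this is checked
#' at construction time and on load.
#'
#' @param metabolites data.frame with columns `id`, `basal` (> 0) and
#'   optionally `co_metabolite` (logical; co-metabolites are held constant
#'   unless a conservation variant is active).
#' @param enzymes data.frame with columns `id`, `basal` (> 0) and optionally
#'   `display_name`.
#' @param rates list of rate laws as returned by [rate_law()].
#' @param stoichiometry numeric matrix (metabolites x rates) with row and
#'   column names matching metabolite and rate ids.
#' @param basal_fluxes named numeric vector of fluxes at the basal state.
#' @param conservation optional conservation specification from
#'   [conservation_spec()].
#' @param name optional model name.
#' @return an object of class `kinetic_model`.
#' @export
kinetic_model <- function(metabolites, enzymes, rates, stoichiometry,
                          basal_fluxes, conservation = NULL, name = "model") {
  metabolites <- as.data.frame(metabolites)
  enzymes <- as.data.frame(enzymes)
  if (is.null(metabolites$co_metabolite)) metabolites$co_metabolite <- FALSE
  if (is.null(enzymes$display_name)) enzymes$display_name <- enzymes$id
  m <- structure(list(
    name = name,
    metabolites = metabolites,
    enzymes = enzymes,
    rates = rates,
    S = stoichiometry,
    basal_fluxes = basal_fluxes,
    conservation = conservation
  ), class = "kinetic_model")
  validate_model(m)
  m$compiled <- compile_model(m)
  m
}

#' Define a single rate law
#'
#' @param id reaction name.
#' @param enzyme id of the enzyme whose activity scales this rate.
#' @param expression character scalar over metabolite ids, the enzyme id and
#'   parameter names, using only `+`, `-`, `*`, `/`, `^` and parentheses.
#' @param kind `"power_law"` (product of power terms) or
#'   `"general_expression"`.
#' @param parameters named numeric vector or list of kinetic parameters.
#' @export
rate_law <- function(id, enzyme, expression, kind = c("power_law", "general_expression"),
                     parameters = list()) {
  kind <- match.arg(kind)
  expr <- parse_rate_expression(expression)
  list(id = id, enzyme = enzyme, kind = kind, expression = expression,
       expr = expr, parameters = as.list(parameters))
}

#' Conservation relations for energy and redox co-metabolites
#'
#' Fixes the adenylate energy charge and the reduced fractions of the
#' NAD and NADP pools at their basal values, so that co-metabolite levels
#' may move jointly instead of being pinned individually.
#'
#' @param roles named character vector mapping the seven roles
#'   `amp, adp, atp, nad, nadh, nadp, nadph` to metabolite ids.
#' @param basal named numeric vector of basal levels for those metabolites.
#' @export
conservation_spec <- function(roles, basal) {
  need <- c("amp", "adp", "atp", "nad", "nadh", "nadp", "nadph")
  if (!all(need %in% names(roles)))
    stop("conservation roles must name all of: ", paste(need, collapse = ", "))
  b <- basal[roles[need]]
  if (anyNA(b) || any(b <= 0))
    stop("missing or non-positive basal level for a conservation co-metabolite")
  c1 <- (b[["atp"]] + 0.5 * b[["adp"]]) / (b[["atp"]] + b[["adp"]] + b[["amp"]])
  c2 <- b[["nadh"]] / (b[["nadh"]] + b[["nad"]])
  c3 <- b[["nadph"]] / (b[["nadph"]] + b[["nadp"]])
  for (ci in c(c1, c2, c3)) if (ci <= 0 || ci >= 1)
    stop("conservation constants must lie strictly in (0, 1)")
  list(roles = roles[need], energy_charge = c1, nadh_fraction = c2,
       nadph_fraction = c3)
}

# ---- expression grammar -----------------------------------------------------

parse_rate_expression <- function(text) {
  expr <- tryCatch(str2lang(text), error = function(e)
    stop("cannot parse rate expression: ", text, call. = FALSE))
  expr
}

# Walk the AST; only arithmetic calls and known symbols are allowed.
check_expression_symbols <- function(expr, allowed, rate_id) {
  ops <- c("+", "-", "*", "/", "^", "(")
  walk <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.symbol(e)) {
      if (!(as.character(e) %in% allowed))
        stop("rate '", rate_id, "': unknown identifier '", as.character(e), "'",
             call. = FALSE)
      return(invisible())
    }
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!(fn %in% ops))
        stop("rate '", rate_id, "': operator '", fn,
             "' is outside the rate-law grammar", call. = FALSE)
      for (i in seq_along(e)[-1]) walk(e[[i]])
      return(invisible())
    }
    stop("rate '", rate_id, "': unsupported expression element", call. = FALSE)
  }
  walk(expr)
}

# ---- validation -------------------------------------------------------------

#' Validate the internal consistency of a kinetic model
#'
#' Checks id uniqueness, positivity, dimensions, the rate-law grammar, the
#' agreement of each rate with its recorded basal flux, and that the basal
#' state is a steady state of \eqn{S v}.
#'
#' @param model a `kinetic_model`.
#' @param tol relative tolerance for basal-flux agreement.
#' @return the model, invisibly; errors describe the offending component.
#' @export
validate_model <- function(model, tol = 1e-6) {
  met <- model$metabolites; enz <- model$enzymes
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(enz$id)) stop("duplicate enzyme ids")
  if (any(met$basal <= 0)) stop("metabolite basal concentrations must be > 0")
  if (any(enz$basal <= 0)) stop("enzyme basal activities must be > 0")
  rate_ids <- vapply(model$rates, `[[`, "", "id")
  if (anyDuplicated(rate_ids)) stop("duplicate rate ids")
  S <- model$S
  if (!is.matrix(S) || nrow(S) != nrow(met) || ncol(S) != length(model$rates))
    stop("stoichiometry dimension mismatch: expected ",
         nrow(met), " x ", length(model$rates), " matrix")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rate_ids))
    stop("stoichiometry row/column names must match metabolite and rate ids")
  if (!all(rate_ids %in% names(model$basal_fluxes)))
    stop("basal_fluxes must cover every rate id")
  for (r in model$rates) {
    if (!(r$enzyme %in% enz$id))
      stop("rate '", r$id, "' references unknown enzyme '", r$enzyme, "'")
    allowed <- c(met$id, r$enzyme, names(r$parameters))
    check_expression_symbols(r$expr, allowed, r$id)
  }
  xb <- stats::setNames(met$basal, met$id)
  eb <- stats::setNames(enz$basal, enz$id)
  v <- evaluate_rates(model, xb, eb)
  vb <- model$basal_fluxes[rate_ids]
  bad <- which(abs(v - vb) > tol * pmax(abs(vb), max(abs(vb))))
  if (length(bad))
    stop("basal-flux mismatch for rate(s): ",
         paste(rate_ids[bad], collapse = ", "))
  dep_rows <- which(!met$co_metabolite)
  resid <- drop(S[dep_rows, , drop = FALSE] %*% v)
  if (max(abs(resid)) > tol * max(abs(vb)))
    stop("basal state is not a steady state (max |S v| = ",
         format(max(abs(resid))), ")")
  invisible(model)
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate all rate laws
#'
#' @param model a `kinetic_model`.
#' @param x named (or model-ordered) vector of concentrations for all
#'   metabolites, co-metabolites included.
#' @param e named (or model-ordered) vector of enzyme activities.
#' @return named flux vector \eqn{v(x, e; \theta)}.
#' @export
evaluate_rates <- function(model, x, e) {
  met_ids <- model$metabolites$id
  enz_ids <- model$enzymes$id
  x <- as_model_vector(x, met_ids, "metabolite")
  e <- as_model_vector(e, enz_ids, "enzyme")
  if (any(e < 0)) stop("enzyme activities must be non-negative")
  env <- list2env(c(as.list(x), as.list(e)))
  v <- vapply(model$rates, function(r) {
    if (r$kind == "power_law" && any(x <= 0))
      stop("non-positive concentration in power-law rate '", r$id, "'")
    for (p in names(r$parameters)) assign(p, r$parameters[[p]], envir = env)
    val <- eval(r$expr, env)
    if (!is.finite(val)) stop("rate '", r$id, "' evaluated to a non-finite value")
    val
  }, numeric(1))
  stats::setNames(v, vapply(model$rates, `[[`, "", "id"))
}

as_model_vector <- function(x, ids, what) {
  if (!is.null(names(x))) {
    if (!all(ids %in% names(x)))
      stop("missing ", what, " value(s): ",
           paste(setdiff(ids, names(x)), collapse = ", "))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop(what, " vector has length ", length(x), ", expected ", length(ids))
  }
  stats::setNames(as.numeric(x), ids)
}

# ---- compilation ------------------------------------------------------------

# Power-law rates are log-linear: kinetic orders are recovered exactly by a
# log-ratio probe (log v(k x_j) - log v(x) = g_j log k for any k). A second
# probe at a different factor certifies log-linearity. Models whose rates are
# all power laws get a fast ratio-space path used throughout the optimizers.
compile_model <- function(model) {
  met <- model$metabolites; enz <- model$enzymes
  xb <- stats::setNames(met$basal, met$id)
  eb <- stats::setNames(enz$basal, enz$id)
  rate_ids <- vapply(model$rates, `[[`, "", "id")
  vb <- model$basal_fluxes[rate_ids]
  dep <- which(!met$co_metabolite); co <- which(met$co_metabolite)
  enzyme_of <- match(vapply(model$rates, `[[`, "", "enzyme"), enz$id)
  all_power <- all(vapply(model$rates, `[[`, "", "kind") == "power_law")
  out <- list(xb = xb, eb = eb, vb = vb, dep = dep, co = co,
              enzyme_of = enzyme_of, rate_ids = rate_ids,
              is_gma = all_power, G = NULL, H = NULL)
  if (all_power) {
    nm <- length(xb)
    K <- matrix(0, length(rate_ids), nm, dimnames = list(rate_ids, met$id))
    v0 <- evaluate_rates(model, xb, eb)
    for (j in seq_len(nm)) {
      x2 <- xb; x2[j] <- xb[j] * 2
      x3 <- xb; x3[j] <- xb[j] * 3
      g2 <- log(evaluate_rates(model, x2, eb) / v0) / log(2)
      g3 <- log(evaluate_rates(model, x3, eb) / v0) / log(3)
      if (max(abs(g2 - g3)) > 1e-8)
        stop("rate declared power_law is not log-linear in '", met$id[j], "'")
      K[, j] <- g2
    }
    # enzyme linearity check (one representative probe per rate)
    for (i in seq_along(model$rates)) {
      e2 <- eb; e2[enzyme_of[i]] <- eb[enzyme_of[i]] * 2
      h <- log(evaluate_rates(model, xb, e2)[i] / v0[i]) / log(2)
      if (abs(h - 1) > 1e-8)
        stop("rate '", rate_ids[i], "' is not first order in its enzyme activity")
    }
    out$G <- K[, dep, drop = FALSE]
    out$H <- K[, co, drop = FALSE]
  }
  out
}

# ---- steady state -----------------------------------------------------------

#' Solve for a steady state at given enzyme activities
#'
#' Damped Newton iteration on the dependent-metabolite balances
#' \eqn{S_{dep} v = 0} in log-concentration space (which preserves
#' positivity), starting from the basal state. Up to `restarts` jittered
#' starting points are tried on failure. Co-metabolites are held at their
#' basal (or supplied) levels.
#'
#' @param model a `kinetic_model`.
#' @param e enzyme activities (absolute units), default basal.
#' @param x0 starting guess for dependent metabolites, default basal.
#' @param co_levels optional replacement co-metabolite levels.
#' @param tol residual tolerance in scaled units (relative to the largest
#'   basal flux).
#' @param max_iter,restarts iteration and jittered-restart limits.
#' @return a `steady_state` object with fields `metabolite_levels`,
#'   `enzyme_levels`, `fluxes`, `residual_norm`, `converged`.
#' @export
steady_state <- function(model, e = NULL, x0 = NULL, co_levels = NULL,
                         tol = 1e-9, max_iter = 200, restarts = 5) {
  cm <- model$compiled
  if (is.null(e)) e <- cm$eb
  e <- as_model_vector(e, model$enzymes$id, "enzyme")
  xb <- cm$xb
  x <- xb
  if (!is.null(co_levels)) {
    co_levels <- as_model_vector(co_levels, names(xb)[cm$co], "co-metabolite")
    x[cm$co] <- co_levels
  }
  if (cm$is_gma) {
    lw <- log(e / cm$eb)[cm$enzyme_of]
    zc <- log(x[cm$co] / xb[cm$co])
    c0 <- lw + if (length(cm$co)) drop(cm$H %*% zc) else 0
    z0 <- if (is.null(x0)) rep(0, length(cm$dep)) else
      log(as_model_vector(x0, names(xb)[cm$dep], "metabolite") / xb[cm$dep])
    sol <- gma_steady(model, c0, z0, tol, max_iter, restarts)
    x[cm$dep] <- xb[cm$dep] * exp(sol$z)
    v <- cm$vb * exp(drop(cm$G %*% sol$z) + c0)
    res <- sol$resid
  } else {
    z0 <- log((if (is.null(x0)) xb[cm$dep] else
      as_model_vector(x0, names(xb)[cm$dep], "metabolite")) / xb[cm$dep])
    sol <- generic_steady(model, e, x, z0, tol, max_iter, restarts)
    x[cm$dep] <- xb[cm$dep] * exp(sol$z)
    v <- evaluate_rates(model, x, e)
    res <- sol$resid
  }
  if (!sol$ok)
    stop("steady state not found (last scaled residual ", format(res), ")")
  structure(list(metabolite_levels = x, enzyme_levels = e,
                 fluxes = stats::setNames(as.numeric(v), cm$rate_ids),
                 residual_norm = res, converged = sol$ok,
                 iterations = sol$it),
            class = "steady_state")
}

# Fast path: residual F(z) = S_dep (vb * exp(G z + c0)); analytic Jacobian.
# Used directly (with warm starts) by the optimization engine.
gma_steady <- function(model, c0, z0, tol = 1e-9, max_iter = 200, restarts = 5) {
  cm <- model$compiled
  Sd <- model$S[cm$dep, , drop = FALSE]
  vb <- as.numeric(cm$vb); G <- cm$G
  vmax <- max(abs(vb))
  z <- z0
  attempt <- 0L
  repeat {
    it <- 0L
    ok <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      v <- vb * exp(drop(G %*% z) + c0)
      FF <- drop(Sd %*% v)
      res <- max(abs(FF)) / vmax
      if (res <= tol) { ok <- TRUE; break }
      J <- Sd %*% (v * G)
      dz <- tryCatch(solve(J, -FF), error = function(err) NULL)
      if (is.null(dz)) break
      f0 <- sum(FF^2); lam <- 1
      repeat {
        zn <- z + lam * dz
        Fn <- drop(Sd %*% (vb * exp(drop(G %*% zn) + c0)))
        if (sum(Fn^2) < f0 || lam < 1e-8) break
        lam <- lam / 2
      }
      if (max(abs(zn)) > 50) break  # diverging
      z <- zn
    }
    if (ok) return(list(z = z, ok = TRUE, resid = res, it = it))
    attempt <- attempt + 1L
    if (attempt > restarts)
      return(list(z = z, ok = FALSE, resid = res, it = it))
    z <- z0 + stats::runif(length(z0), -0.3, 0.3) * attempt
  }
}

# General rate laws: numeric Jacobian by central differences in log space.
generic_steady <- function(model, e, x_full, z0, tol, max_iter, restarts) {
  cm <- model$compiled
  Sd <- model$S[cm$dep, , drop = FALSE]
  xb_dep <- cm$xb[cm$dep]
  vmax <- max(abs(cm$vb))
  resid_fun <- function(z) {
    x <- x_full; x[cm$dep] <- xb_dep * exp(z)
    drop(Sd %*% evaluate_rates(model, x, e))
  }
  z <- z0; attempt <- 0L
  repeat {
    it <- 0L; ok <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      FF <- resid_fun(z)
      res <- max(abs(FF)) / vmax
      if (res <= tol) { ok <- TRUE; break }
      n <- length(z); J <- matrix(0, n, n)
      h <- 1e-6
      for (j in seq_len(n)) {
        zp <- z; zp[j] <- z[j] + h
        zm <- z; zm[j] <- z[j] - h
        J[, j] <- (resid_fun(zp) - resid_fun(zm)) / (2 * h)
      }
      dz <- tryCatch(solve(J, -FF), error = function(err) NULL)
      if (is.null(dz)) break
      f0 <- sum(FF^2); lam <- 1
      repeat {
        zn <- z + lam * dz
        if (sum(resid_fun(zn)^2) < f0 || lam < 1e-8) break
        lam <- lam / 2
      }
      if (max(abs(zn)) > 50) break
      z <- zn
    }
    if (ok) return(list(z = z, ok = TRUE, resid = res, it = it))
    attempt <- attempt + 1L
    if (attempt > restarts) return(list(z = z, ok = FALSE, resid = res, it = it))
    z <- z0 + stats::runif(length(z0), -0.3, 0.3) * attempt
  }
}

#' Conservation residuals for the co-metabolite pools
#'
#' Left-minus-right residuals of the three conservation relations (energy
#' charge, NADH fraction, NADPH fraction) at the supplied co-metabolite
#' levels.
#'
#' @param model a `kinetic_model` with a conservation block.
#' @param co_levels named vector covering the seven co-metabolite ids.
#' @export
conservation_residuals <- function(model, co_levels) {
  cs <- model$conservation
  if (is.null(cs)) stop("model has no conservation specification")
  need <- unname(cs$roles)
  if (!all(need %in% names(co_levels)))
    stop("missing co-metabolite level(s): ",
         paste(setdiff(need, names(co_levels)), collapse = ", "))
  b <- co_levels[cs$roles]
  names(b) <- names(cs$roles)
  if (any(b <= 0)) stop("co-metabolite levels must be positive")
  c(energy_charge = unname((b["atp"] + 0.5 * b["adp"]) /
                             (b["atp"] + b["adp"] + b["amp"]) - cs$energy_charge),
    nadh_fraction = unname(b["nadh"] / (b["nadh"] + b["nad"]) - cs$nadh_fraction),
    nadph_fraction = unname(b["nadph"] / (b["nadph"] + b["nadp"]) - cs$nadph_fraction))
}

#' Spectral abscissa of the Jacobian at a steady state
#'
#' Optional stability diagnostic: the largest real part among eigenvalues of
#' \eqn{d(Sv)/dx} restricted to dependent metabolites. Negative values
#' indicate local asymptotic stability. Stability is reported, never
#' enforced.
#'
#' @param model a `kinetic_model`.
#' @param state a `steady_state`.
#' @export
stability_diagnostic <- function(model, state) {
  cm <- model$compiled
  x <- state$metabolite_levels; e <- state$enzyme_levels
  Sd <- model$S[cm$dep, , drop = FALSE]
  n <- length(cm$dep)
  J <- matrix(0, n, n)
  v0 <- evaluate_rates(model, x, e)
  for (j in seq_len(n)) {
    h <- 1e-6 * x[cm$dep[j]]
    xp <- x; xp[cm$dep[j]] <- x[cm$dep[j]] + h
    J[, j] <- drop(Sd %*% (evaluate_rates(model, xp, e) - v0)) / h
  }
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady state: residual", format(x$residual_norm, digits = 3),
      "in", x$iterations, "iterations\n")
  cat("  metabolites:", paste(sprintf("%s=%.4g", names(x$metabolite_levels),
                                      x$metabolite_levels), collapse = ", "), "\n")
  invisible(x)
}
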