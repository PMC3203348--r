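# Membership functions grading fuzzy goals on [0, 1], and the
# delta-augmented min-max goal-attainment aggregation.

#' Membership function specification
#'
#' @param kind `"maximize"` (monotone increasing between two anchors),
#'   `"equal"` (peaked at a central anchor, zero at the outer anchors) or
#'   `"inequality"` (monotone decreasing between two anchors).
#' @param anchors numeric anchors, strictly increasing: two values for
#'   `maximize`/`inequality`, three (`lower`, `center`, `upper`) for
#'   `equal`.
#' @param shape grading shape between anchors: `"linear"` (default),
#'   `"exponential"`, `"hyperbolic"`, `"inverse"` or `"piecewise_linear"`.
#' @export
membership_spec <- function(kind = c("maximize", "equal", "inequality"),
                            anchors, shape = "linear") {
  kind <- match.arg(kind)
  shape <- match.arg(shape, c("linear", "exponential", "hyperbolic",
                              "inverse", "piecewise_linear"))
  n_need <- if (kind == "equal") 3L else 2L
  if (length(anchors) != n_need)
    stop(kind, " membership needs ", n_need, " anchors")
  if (any(diff(anchors) <= 0))
    stop("membership anchors must be strictly increasing")
  structure(list(kind = kind, anchors = as.numeric(anchors), shape = shape),
            class = "membership_spec")
}

# Shape transforms map a normalized coordinate t in [0,1] to a grade in
# [0,1], fixing the endpoints. Only the linear shape is calibrated against
# published results; the others follow standard fuzzy-set forms.
shape_transform <- function(t, shape) {
  t <- pmin(pmax(t, 0), 1)
  switch(shape,
    linear = t,
    exponential = (1 - exp(-2 * t)) / (1 - exp(-2)),
    hyperbolic = (tanh(4 * (t - 0.5)) + tanh(2)) / (2 * tanh(2)),
    inverse = 2 * t / (1 + t),
    piecewise_linear = ifelse(t <= 0.5, 0.5 * t, 1.5 * t - 0.5))
}

#' Grade a fuzzy maximization goal
#'
#' Zero at or below the lower anchor, one at or above the upper anchor,
#' monotone increasing between.
#'
#' @param f the goal value (e.g. a flux ratio).
#' @param spec a `membership_spec` with `kind = "maximize"`.
#' @export
membership_maximize <- function(f, spec) {
  stopifnot(inherits(spec, "membership_spec"), spec$kind == "maximize")
  a <- spec$anchors
  shape_transform((f - a[1]) / (a[2] - a[1]), spec$shape)
}

#' Grade a fuzzy-equal (resilience) goal
#'
#' One exactly at the central anchor (the wild-type level), falling to zero
#' at or beyond either outer anchor; monotone toward the center on each
#' side. With the linear shape this is the usual triangular membership.
#'
#' @param value the observed level.
#' @param spec a `membership_spec` with `kind = "equal"`.
#' @export
membership_equal <- function(value, spec) {
  stopifnot(inherits(spec, "membership_spec"), spec$kind == "equal")
  a <- spec$anchors
  lo <- shape_transform((value - a[1]) / (a[2] - a[1]), spec$shape)
  hi <- shape_transform((a[3] - value) / (a[3] - a[2]), spec$shape)
  ifelse(value <= a[2], lo, hi)
}

#' Grade a soft viability (fuzzy inequality) constraint
#'
#' One at or below the lower anchor, zero at or above the upper anchor,
#' monotone decreasing between. A grade of exactly zero marks a non-viable
#' (infeasible) solution.
#'
#' @param total the summed level (e.g. total metabolite concentration).
#' @param spec a `membership_spec` with `kind = "inequality"`.
#' @export
membership_viability <- function(total, spec) {
  stopifnot(inherits(spec, "membership_spec"), spec$kind == "inequality")
  a <- spec$anchors
  shape_transform((a[2] - total) / (a[2] - a[1]), spec$shape)
}

#' Augmented min-max goal attainment
#'
#' Aggregates membership grades into the scalar
#' \deqn{\eta_D = \max_i (\bar\eta_i - \eta_i) + \delta \sum_i (\bar\eta_i - \eta_i),}
#' where \eqn{\bar\eta_i} are the ideal grades. Smaller is better; the
#' augmentation term breaks ties among points with the same worst
#' deviation.
#'
#' @param grades named (or plain) numeric membership grades.
#' @param ideals ideal grades, recycled to the grades.
#' @param delta small positive augmentation weight.
#' @export
goal_attainment <- function(grades, ideals = 1, delta = 1e-4) {
  if (length(grades) == 0) stop("goal_attainment needs at least one grade")
  if (!is.null(names(ideals)) && !is.null(names(grades))) {
    if (!all(names(grades) %in% names(ideals)))
      stop("grades and ideals must share names")
    ideals <- ideals[names(grades)]
  } else ideals <- rep_len(ideals, length(grades))
  dev <- ideals - grades
  max(dev) + delta * sum(dev)
}
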