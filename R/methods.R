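# S3 methods for reporting solutions, fronts and study objects.

#' @export
print.fmoop_solution <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<failed solve:", x$reason, ">\n")
    return(invisible(x))
  }
  cat(sprintf("%s solution (%d modulated enzyme%s%s)\n",
              switch(x$problem_type, primal = "Primal", soop = "Single-objective",
                     fuzzy = "Resilience", x$problem_type),
              sum(x$pattern$y), if (sum(x$pattern$y) == 1) "" else "s",
              if (!is.null(x$epsilon)) paste0(", budget ", x$epsilon) else ""))
  cat("  modulated:", paste(x$modulated, collapse = ", "), "\n")
  for (i in seq_along(x$flux_ratios))
    cat(sprintf("  %s flux ratio: %.4f\n", names(x$flux_ratios)[i],
                x$flux_ratios[i]))
  if (!is.na(x$eta_D)) cat(sprintf("  eta_D: %.4f\n", x$eta_D))
  cat("  feasible:", x$feasible, "\n")
  invisible(x)
}

#' @export
summary.fmoop_solution <- function(object, ...) {
  print(object)
  cat("\nEnzyme activity ratios:\n")
  er <- object$enzyme_ratios
  mod <- object$pattern$y == 1L
  for (i in order(-mod, -abs(log(er)))) {
    if (abs(log(er[i])) < 1e-6 && !mod[i]) next
    cat(sprintf("  %-10s %6.3f %s\n", names(er)[i], er[i],
                if (mod[i]) "(modulated)" else ""))
  }
  cat("\nMetabolite concentration ratios:\n")
  mr <- object$metabolite_ratios
  for (i in seq_along(mr)) cat(sprintf("  %-10s %6.3f\n", names(mr)[i], mr[i]))
  cat(sprintf("\nTotals vs basal: metabolites %.3f, enzymes %.3f\n",
              object$totals["metabolite"], object$totals["enzyme"]))
  if (!is.null(object$memberships)) {
    cat("\nMembership grades:\n")
    for (i in seq_along(object$memberships))
      cat(sprintf("  %-14s %.4f\n", names(object$memberships)[i],
                  object$memberships[i]))
  }
  invisible(object)
}

#' @export
coef.fmoop_solution <- function(object, ...) object$enzyme_ratios

#' @export
print.fmoop_front <- function(x, ...) {
  cat(sprintf("%s Pareto front over the enzyme budget (%d rows)\n",
              if (attr(x, "problem") == "primal") "Primal" else "Resilience",
              nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a Pareto front (and its feasible point cloud)
#'
#' @param x an `fmoop_front`.
#' @param target target ratio column to plot (default: first target).
#' @param cloud draw per-pattern feasible optima behind the front.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fmoop_front <- function(x, target = NULL, cloud = TRUE, ...) {
  tgt <- target %||% attr(x, "targets")[1]
  col <- paste0("ratio_", tgt)
  cl <- attr(x, "cloud")
  ylim <- range(x[[col]], if (cloud && !is.null(cl))
    vapply(cl, function(s) if (!s$failed && s$feasible)
      s$flux_ratios[[tgt]] else NA_real_, 1), 1, na.rm = TRUE)
  graphics::plot(x$epsilon, x[[col]], type = "b", pch = 19,
                 xlab = "allowed number of modulated enzymes",
                 ylab = paste(tgt, "flux ratio"), ylim = ylim, ...)
  if (cloud && !is.null(cl)) {
    pts <- do.call(rbind, lapply(cl, function(s) {
      if (s$failed || !s$feasible) return(NULL)
      c(sum(s$pattern$y), s$flux_ratios[[tgt]])
    }))
    if (!is.null(pts)) graphics::points(pts[, 1], pts[, 2], col = "grey60",
                                        cex = 0.6)
    graphics::lines(x$epsilon, x[[col]], type = "b", pch = 19)
  }
  invisible(x)
}
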