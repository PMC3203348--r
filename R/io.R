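# Model file I/O. One structured JSON dialect ("kinetic-model/1"):
#   schema, name,
#   metabolites: [{id, basal, co_metabolite}],
#   enzymes:     [{id, basal, display_name}],
#   stoichiometry: {metabolites: [...], rates: [...], matrix: [[...]]},
#   rates: [{id, enzyme, kind, expression, parameters{}}],
#   basal_fluxes: {rate: value},
#   conservation (optional): {roles{}, ...constants recomputed on load}
# Expressions use the +,-,*,/,^,() grammar over declared identifiers only.

MODEL_SCHEMA <- "kinetic-model/1"

#' Read a kinetic model from a JSON file
#'
#' Loading validates the full model, including the requirement that the
#' recorded basal state is a steady state; malformed files fail with an
#' error naming the offending component.
#'
#' @param path file path.
#' @return a `kinetic_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema) || !identical(doc$schema, MODEL_SCHEMA))
    stop("unsupported model schema: ", doc$schema %||% "<missing>")
  met <- data.frame(
    id = vapply(doc$metabolites, `[[`, "", "id"),
    basal = vapply(doc$metabolites, `[[`, 1, "basal"),
    co_metabolite = vapply(doc$metabolites, function(x)
      isTRUE(x$co_metabolite), TRUE))
  enz <- data.frame(
    id = vapply(doc$enzymes, `[[`, "", "id"),
    basal = vapply(doc$enzymes, `[[`, 1, "basal"),
    display_name = vapply(doc$enzymes, function(x)
      x$display_name %||% x$id, ""))
  st <- doc$stoichiometry
  met_ids <- unlist(st$metabolites); rate_ids <- unlist(st$rates)
  rows <- lapply(st$matrix, unlist)
  if (length(rows) != length(met_ids) ||
      any(vapply(rows, length, 0L) != length(rate_ids)))
    stop("stoichiometry matrix shape does not match its declared ",
         length(met_ids), " metabolites x ", length(rate_ids), " rates")
  S <- do.call(rbind, rows)
  dimnames(S) <- list(met_ids, rate_ids)
  rates <- lapply(doc$rates, function(r)
    rate_law(id = r$id, enzyme = r$enzyme, expression = r$expression,
             kind = r$kind,
             parameters = lapply(r$parameters %||% list(), as.numeric)))
  cons <- NULL
  if (!is.null(doc$conservation)) {
    roles <- unlist(doc$conservation$roles)
    basal <- stats::setNames(met$basal, met$id)
    cons <- conservation_spec(roles, basal)
  }
  kinetic_model(metabolites = met, enzymes = enz, rates = rates,
                stoichiometry = S,
                basal_fluxes = unlist(doc$basal_fluxes),
                conservation = cons,
                name = doc$name %||% basename(path))
}

#' Write a kinetic model to a JSON file
#'
#' `load_model(save_model(m, path))` reproduces every field of `m`.
#'
#' @param model a `kinetic_model`.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  df_rows <- function(df) lapply(seq_len(nrow(df)), function(i)
    as.list(df[i, , drop = FALSE]))
  doc <- list(
    schema = MODEL_SCHEMA,
    name = model$name,
    metabolites = df_rows(model$metabolites[c("id", "basal", "co_metabolite")]),
    enzymes = df_rows(model$enzymes[c("id", "basal", "display_name")]),
    stoichiometry = list(metabolites = rownames(model$S),
                         rates = colnames(model$S),
                         matrix = lapply(seq_len(nrow(model$S)), function(i)
                           unname(model$S[i, ]))),
    rates = lapply(model$rates, function(r)
      list(id = r$id, enzyme = r$enzyme, kind = r$kind,
           expression = r$expression, parameters = r$parameters)),
    basal_fluxes = as.list(model$basal_fluxes)
  )
  if (!is.null(model$conservation))
    doc$conservation <- list(roles = as.list(model$conservation$roles))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled yeast anaerobic fermentation model
#'
#' Generalized mass action model of anaerobic glucose fermentation in
#' \emph{S. cerevisiae} (glucose uptake through ethanol secretion with
#' glycerol and storage-carbohydrate branches): 5 dependent metabolites and
#' 8 enzyme-scaled power-law rates. Reconstructed from the published model
#' of Curto and co-workers; see the package vignette for provenance notes.
#'
#' @return a `kinetic_model`.
#' @export
yeast_model <- function() {
  load_model(system.file("extdata", "yeast_fermentation_gma.json",
                         package = "enzopt", mustWork = TRUE))
}

#' Bundled synthetic E. coli central-carbon model
#'
#' A synthetic generalized-mass-action stand-in with the topology of the
#' central carbon metabolism of \emph{E. coli} (PTS uptake, glycolysis,
#' pentose-phosphate pathway and amino-acid drains): 18 dependent
#' metabolites, 30 enzymatic reactions and 7 co-metabolites held constant
#' by default. The kinetic orders are plausible but synthetic; quantitative
#' results on this fixture characterize the method, not the organism.
#'
#' @return a `kinetic_model`.
#' @export
ecoli_model <- function() {
  load_model(system.file("extdata", "ecoli_ccm_synthetic.json",
                         package = "enzopt", mustWork = TRUE))
}
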