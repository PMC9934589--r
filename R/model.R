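# Metabolic model container.
#
# A model is a plain list with class "metabolic_model":
#   id            model identifier
#   metabolites   data.frame(id, name, compartment)
#   reactions     data.frame(id, lower_bound, upper_bound, subsystem)
#   stoichiometry named list (per reaction) of named numeric coefficients,
#                 negative = consumed, positive = produced
#   gpr           named list (per reaction) of gpr_rule trees
#   objective_id  reaction id of the objective
#
# Flux bounds are nominally mmol/gDW/h and must be finite (the built-in LP
# solver works on bounded polytopes; use a large box such as +/-1000 for
# effectively unconstrained reactions).

#' Construct a metabolic model
#'
#' @param id Model identifier.
#' @param metabolites `data.frame` with columns `id`, `name`, `compartment`.
#' @param reactions `data.frame` with columns `id`, `lower_bound`,
#'   `upper_bound`, `subsystem` (empty string allowed).
#' @param stoichiometry Named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param gpr Named list, one entry per reaction id, each a `gpr_rule` (use
#'   the empty rule for reactions without gene association). Defaults to all
#'   empty rules.
#' @param objective_id Reaction id of the objective reaction.
#' @return A validated `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            gpr = NULL, objective_id) {
  if (is.null(gpr)) {
    gpr <- stats::setNames(replicate(nrow(reactions), gpr_empty(),
                                     simplify = FALSE), reactions$id)
  }
  m <- structure(list(
    id = id,
    metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
    reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
    stoichiometry = stoichiometry,
    gpr = gpr,
    objective_id = objective_id
  ), class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, stoichiometry references, bound ordering and
#' finiteness, GPR classes, and existence of the objective reaction.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; signals `tidegem_validation_error` on
#'   failure.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions
  bad <- function(fmt, ...) abort_(fmt, ..., class = "tidegem_validation_error")

  for (col in c("id", "name", "compartment"))
    if (!col %in% names(met)) bad("metabolites lack column '%s'", col)
  for (col in c("id", "lower_bound", "upper_bound", "subsystem"))
    if (!col %in% names(rxn)) bad("reactions lack column '%s'", col)

  if (any(!nzchar(met$id))) bad("empty metabolite id")
  if (any(!nzchar(rxn$id))) bad("empty reaction id")
  if (anyDuplicated(met$id)) bad("duplicate metabolite id '%s'",
                                 met$id[duplicated(met$id)][1])
  if (anyDuplicated(rxn$id)) bad("duplicate reaction id '%s'",
                                 rxn$id[duplicated(rxn$id)][1])
  if (!setequal(names(model$stoichiometry), rxn$id))
    bad("stoichiometry entries do not match reaction ids")
  if (!setequal(names(model$gpr), rxn$id))
    bad("gpr entries do not match reaction ids")
  for (rid in rxn$id) {
    s <- model$stoichiometry[[rid]]
    if (length(s) == 0L) bad("reaction '%s' has empty stoichiometry", rid)
    miss <- setdiff(names(s), met$id)
    if (length(miss)) bad("reaction '%s' references undefined metabolite '%s'",
                          rid, miss[1])
    if (!inherits(model$gpr[[rid]], "gpr_rule"))
      bad("reaction '%s' has an invalid GPR", rid)
  }
  if (any(!is.finite(rxn$lower_bound)) || any(!is.finite(rxn$upper_bound)))
    bad("non-finite flux bound")
  if (any(rxn$lower_bound > rxn$upper_bound))
    bad("lower bound exceeds upper bound for reaction '%s'",
        rxn$id[rxn$lower_bound > rxn$upper_bound][1])
  if (!model$objective_id %in% rxn$id)
    bad("objective reaction '%s' not in model", model$objective_id)
  invisible(model)
}

#' Genes of a model
#' @param model A `metabolic_model`.
#' @return Sorted character vector of all GPR leaf gene ids.
#' @export
model_genes <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  sort(unique(unlist(lapply(model$gpr, gpr_genes), use.names = FALSE)))
}

#' Stoichiometric matrix of a model
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    s <- model$stoichiometry[[rid]]
    S[names(s), rid] <- s
  }
  S
}

#' Exchange reactions of a model
#'
#' Boundary reactions are identified structurally as reactions touching a
#' single metabolite (pure sources/sinks).
#'
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  ids <- model$reactions$id
  ids[vapply(model$stoichiometry[ids], length, integer(1)) == 1L]
}

#' Remove reactions (and orphaned metabolites) from a model
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to drop. The objective reaction cannot be dropped.
#' @return The reduced, re-validated model.
#' @export
remove_reactions <- function(model, ids) {
  stopifnot(inherits(model, "metabolic_model"))
  if (model$objective_id %in% ids)
    abort_("cannot remove the objective reaction '%s'", model$objective_id,
           class = "tidegem_validation_error")
  keep <- setdiff(model$reactions$id, ids)
  model$reactions <- model$reactions[model$reactions$id %in% keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[keep]
  model$gpr <- model$gpr[keep]
  used <- unique(unlist(lapply(model$stoichiometry, names), use.names = FALSE))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                         drop = FALSE]
  rownames(model$metabolites) <- NULL
  validate_model(model)
  model
}

#' Set the flux bounds of one reaction
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param lower,upper New bounds (either may be `NULL` to keep the current
#'   value).
#' @return The modified, re-validated model.
#' @export
set_reaction_bounds <- function(model, id, lower = NULL, upper = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  i <- match(id, model$reactions$id)
  if (is.na(i)) abort_("unknown reaction '%s'", id,
                       class = "tidegem_validation_error")
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  validate_model(model)
  model
}

#' Check a flux vector against steady state and bounds
#'
#' @param model A `metabolic_model`.
#' @param flux Named numeric vector over all model reactions.
#' @param tol Steady-state and bound tolerance (default `1e-6`).
#' @return List with `feasible` (logical), `max_residual` (max-norm of
#'   `S v`), and `bound_violation`.
#' @export
check_steady_state <- function(model, flux, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  v <- flux[model$reactions$id]
  resid <- as.vector(stoich_matrix(model) %*% v)
  bv <- max(0, model$reactions$lower_bound - v, v - model$reactions$upper_bound)
  list(feasible = max(abs(resid)) <= tol && bv <= tol,
       max_residual = max(abs(resid)), bound_violation = bv)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d reactions, %d metabolites, %d genes, %d subsystems>\n",
              x$id, nrow(x$reactions), nrow(x$metabolites),
              length(model_genes(x)),
              length(unique(x$reactions$subsystem[nzchar(x$reactions$subsystem)]))))
  cat(sprintf("  objective: %s\n", x$objective_id))
  invisible(x)
}
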