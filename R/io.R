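# Model I/O: a flat JSON dialect mirroring the container fields, and SBML
# Level 3 Version 1 with the fbc package (GPRs as geneProductAssociation,
# bounds as parameters) plus the groups package for subsystem labels, the
# convention used by Human1-style reconstructions. Ids are written with the
# conventional M_/R_/G_ prefixes and stripped on read.

SBML_NS    <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC   <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS<- "http://www.sbml.org/sbml/level3/version1/groups/version1"

#' Read a metabolic model from disk
#'
#' @param path File path.
#' @param format `"json"`, `"sbml"`, or `NULL` to infer from the extension
#'   (`.json` vs `.xml`/`.sbml`).
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path))
    abort_("model file '%s' does not exist", path, class = "tidegem_io_error")
  format <- format %||% switch(tolower(tools::file_ext(path)),
    json = "json", xml = "sbml", sbml = "sbml",
    abort_("cannot infer model format from '%s'", path,
           class = "tidegem_io_error"))
  switch(match.arg(format, c("json", "sbml")),
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format `"json"` or `"sbml"`; inferred from the extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  validate_model(model)
  format <- format %||% switch(tolower(tools::file_ext(path)),
    json = "json", xml = "sbml", sbml = "sbml",
    abort_("cannot infer model format from '%s'", path,
           class = "tidegem_io_error"))
  switch(match.arg(format, c("json", "sbml")),
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
    error = function(e) abort_("JSON parse failure in '%s': %s", path,
                               conditionMessage(e), class = "tidegem_io_error"))
  for (field in c("id", "objective", "metabolites", "reactions"))
    if (is.null(doc[[field]]))
      abort_("model JSON lacks field '%s'", field, class = "tidegem_io_error")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment %||% "c",
    stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) data.frame(
    id = r$id, lower_bound = as.numeric(r$lower_bound),
    upper_bound = as.numeric(r$upper_bound),
    subsystem = r$subsystem %||% "", stringsAsFactors = FALSE)))
  stoich <- stats::setNames(lapply(doc$reactions, function(r) {
    s <- unlist(r$stoichiometry)
    stats::setNames(as.numeric(s), names(s))
  }), rxns$id)
  gpr <- stats::setNames(lapply(doc$reactions, function(r)
    parse_gpr(r$gpr %||% "")), rxns$id)
  metabolic_model(doc$id, mets, rxns, stoich, gpr, doc$objective)
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    objective = model$objective_id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      as.list(model$metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(model$reactions$id, function(rid) {
      i <- match(rid, model$reactions$id)
      list(id = rid,
           stoichiometry = as.list(model$stoichiometry[[rid]]),
           lower_bound = model$reactions$lower_bound[i],
           upper_bound = model$reactions$upper_bound[i],
           gpr = gpr_to_string(model$gpr[[rid]]),
           subsystem = model$reactions$subsystem[i])
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

gpr_to_fbc <- function(rule, parent) {
  if (rule$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", rule$gene))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", rule$kind))
    for (ch in rule$children) gpr_to_fbc(ch, node)
  }
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = SBML_FBC, "xmlns:groups" = SBML_GROUPS,
    level = "3", version = "1", "fbc:required" = "false",
    "groups:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(ls, "species", id = paste0("M_", m$id), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
  }

  genes <- model_genes(model)
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                          "fbc:label" = g)
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    xml2::xml_add_child(lp, "parameter", id = paste0("P_lb_", rid),
      value = format(model$reactions$lower_bound[i], digits = 17),
      constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("P_ub_", rid),
      value = format(model$reactions$upper_bound[i], digits = 17),
      constant = "true")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    rx <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", rid),
      reversible = tolower(model$reactions$lower_bound[i] < 0), fast = "false",
      "fbc:lowerFluxBound" = paste0("P_lb_", rid),
      "fbc:upperFluxBound" = paste0("P_ub_", rid))
    s <- model$stoichiometry[[rid]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      n1 <- xml2::xml_add_child(rx, "listOfReactants")
      for (mid in names(reac))
        xml2::xml_add_child(n1, "speciesReference",
          species = paste0("M_", mid),
          stoichiometry = format(-reac[[mid]], digits = 17), constant = "true")
    }
    if (length(prod)) {
      n2 <- xml2::xml_add_child(rx, "listOfProducts")
      for (mid in names(prod))
        xml2::xml_add_child(n2, "speciesReference",
          species = paste0("M_", mid),
          stoichiometry = format(prod[[mid]], digits = 17), constant = "true")
    }
    rule <- model$gpr[[rid]]
    if (!gpr_is_empty(rule)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      gpr_to_fbc(rule, ga)
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
    "fbc:reaction" = paste0("R_", model$objective_id), "fbc:coefficient" = "1")

  subs <- unique(model$reactions$subsystem[nzchar(model$reactions$subsystem)])
  if (length(subs)) {
    lgp <- xml2::xml_add_child(mdl, "groups:listOfGroups")
    for (k in seq_along(subs)) {
      gr <- xml2::xml_add_child(lgp, "groups:group",
        "groups:id" = sprintf("group%d", k), "groups:kind" = "partonomy",
        "groups:name" = subs[k])
      lm <- xml2::xml_add_child(gr, "groups:listOfMembers")
      for (rid in model$reactions$id[model$reactions$subsystem == subs[k]])
        xml2::xml_add_child(lm, "groups:member",
                            "groups:idRef" = paste0("R_", rid))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

fbc_to_gpr <- function(node) {
  nm <- xml2::xml_name(node)  # local name
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(gpr_gene(strip_prefix(g, "G_")))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(gpr_node(nm, lapply(kids, fbc_to_gpr)))
  }
  abort_("unsupported element '%s' in geneProductAssociation", nm,
         class = "tidegem_io_error")
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) abort_("SBML parse failure in '%s': %s", path,
                               conditionMessage(e), class = "tidegem_io_error"))
  ns <- c(s = SBML_NS, fbc = SBML_FBC, g = SBML_GROUPS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    abort_("no <model> element in '%s'", path, class = "tidegem_io_error")

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  # subsystems from groups
  sub_of <- character(0)
  for (gr in xml2::xml_find_all(mdl, ".//g:listOfGroups/g:group", ns)) {
    nm <- xml2::xml_attr(gr, "name")
    ids <- xml2::xml_attr(xml2::xml_find_all(gr, ".//g:member", ns), "idRef")
    sub_of[strip_prefix(ids, "R_")] <- nm
  }

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L)
    abort_("no reactions in '%s'", path, class = "tidegem_io_error")
  ids <- strip_prefix(xml2::xml_attr(rx, "id"), "R_")
  lb <- ub <- numeric(length(rx))
  stoich <- vector("list", length(rx)); gpr <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || !lbp %in% names(parval) ||
        !ubp %in% names(parval))
      abort_("reaction '%s' lacks resolvable flux bounds", ids[i],
             class = "tidegem_io_error")
    lb[i] <- parval[[lbp]]; ub[i] <- parval[[ubp]]
    reac <- xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns)
    s <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(prod, "species"), "M_")))
    if (length(s) == 0L)
      abort_("reaction '%s' has no reactants or products", ids[i],
             class = "tidegem_io_error")
    stoich[[i]] <- s
    ga <- xml2::xml_find_first(r, ".//fbc:geneProductAssociation", ns)
    gpr[[i]] <- if (inherits(ga, "xml_missing")) gpr_empty() else {
      kids <- xml2::xml_children(ga)
      if (length(kids) != 1L)
        abort_("malformed geneProductAssociation in reaction '%s'", ids[i],
               class = "tidegem_io_error")
      fbc_to_gpr(kids[[1L]])
    }
  }

  fo <- xml2::xml_find_first(mdl, ".//fbc:listOfObjectives//fbc:fluxObjective",
                             ns)
  if (inherits(fo, "xml_missing"))
    abort_("no flux objective in '%s'", path, class = "tidegem_io_error")
  objective <- strip_prefix(xml2::xml_attr(fo, "reaction"), "R_")

  rxns <- data.frame(id = ids, lower_bound = lb, upper_bound = ub,
                     subsystem = ifelse(is.na(sub_of[ids]), "", sub_of[ids]),
                     stringsAsFactors = FALSE)
  metabolic_model(xml2::xml_attr(mdl, "id") %||% "model", mets, rxns,
                  stats::setNames(stoich, ids), stats::setNames(gpr, ids),
                  objective)
}
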