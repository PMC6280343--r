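#' Lossless native JSON serialization of a draft model
#'
#' Writes every field of a [draft_model] (metabolites, reactions with
#' stoichiometry and annotations, compartments, provenance) to JSON;
#' [read_model_json()] reconstructs an identical model, including the
#' sparse stoichiometric matrix, so the pair round-trips exactly.
#'
#' @param model a [draft_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    list(model_id = r$model_id, kegg_id = r$kegg_id, name = r$name,
         equation = r$equation, gpr = r$gpr, rxn_attention = r$rxn_attention,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         reversible = r$reversible,
         stoichiometry = as.list(r$stoichiometry[[1]]),
         annotations = r$annotations[[1]])
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(model_id = m$model_id, kegg_id = m$kegg_id, name = m$name,
         formula = m$formula, compartment = m$compartment)
  })
  out <- list(model_id = model$model_id, kind = model$kind,
              compartments = as.list(model$compartments),
              metabolites = mets, reactions = rxns,
              provenance = model$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(model_id = m$model_id, kegg_id = m$kegg_id, name = m$name,
               formula = m$formula, compartment = m$compartment,
               stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(x$reactions, function(r)
    data.frame(model_id = r$model_id, kegg_id = r$kegg_id, name = r$name,
               equation = r$equation, gpr = r$gpr,
               rxn_attention = r$rxn_attention,
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               reversible = r$reversible, stringsAsFactors = FALSE)))
  rxns$stoichiometry <- lapply(x$reactions, function(r)
    stats::setNames(vapply(r$stoichiometry, as.numeric, 0),
                    names(r$stoichiometry)))
  rxns$annotations <- lapply(x$reactions, function(r) {
    ann <- r$annotations
    ann$ec_numbers <- as.character(unlist(ann$ec_numbers))
    ann$gene_sources <- as.character(unlist(ann$gene_sources))
    ann
  })
  prov <- x$provenance
  prov$organisms <- as.character(unlist(prov$organisms))
  new_draft_model(x$model_id, x$kind, mets, rxns,
                  compartments = unlist(x$compartments), provenance = prov)
}

sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a draft model as SBML Level 3 Version 1 with the fbc extension
#'
#' Species, reactions and gene products are written with `fbc` strict
#' semantics: bounds as global parameters, GPRs as `fbc:or` gene-product
#' associations, KEGG IDs as identifiers.org CV terms (RDF annotation),
#' and non-standard data (the `rxn_attention` field) in notes.  KEGG
#' gene IDs contain a colon, which is not a valid SId character, so IDs
#' are sanitized for SId positions while the verbatim forms stay in the
#' model's annotations.
#'
#' @param model a [draft_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    "xmlns:rdf" = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    "xmlns:bqbiol" = "http://biomodels.net/biology-qualifiers/",
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = sbml_sid(model$model_id),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in names(model$compartments)) {
    xml2::xml_add_child(comps, "compartment", id = sbml_sid(cid),
                        name = model$compartments[[cid]], constant = "true")
  }

  species <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      species, "species",
      id = paste0("M_", sbml_sid(m$model_id)), name = m$name,
      compartment = sbml_sid(m$compartment),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (nzchar(m$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", gsub("[^A-Za-z0-9]", "", m$formula))
    add_cv_term(sp, "compound", m$kegg_id)
  }

  params <- xml2::xml_add_child(mdl, "listOfParameters")
  xml2::xml_add_child(params, "parameter", id = "lb", constant = "true",
                      value = format(-DEFAULT_BOUND))
  xml2::xml_add_child(params, "parameter", id = "ub", constant = "true",
                      value = format(DEFAULT_BOUND))

  genes <- sort(unique(unlist(strsplit(model$reactions$gpr, " or ", fixed = TRUE))))
  genes <- genes[nzchar(genes)]
  if (length(genes)) {
    glist <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(glist, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_sid(g)),
                          "fbc:label" = g)
    }
  }

  rlist <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    rx <- xml2::xml_add_child(
      rlist, "reaction", id = paste0("R_", sbml_sid(r$model_id)),
      name = r$name, reversible = "true", fast = "false",
      "fbc:lowerFluxBound" = "lb", "fbc:upperFluxBound" = "ub")
    if (nzchar(r$rxn_attention)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("rxnAttention: ", r$rxn_attention))
    }
    add_cv_term(rx, "reaction", r$kegg_id)
    st <- r$stoichiometry[[1]]
    reac <- xml2::xml_add_child(rx, "listOfReactants")
    prod <- xml2::xml_add_child(rx, "listOfProducts")
    for (met in names(st)) {
      parent <- if (st[[met]] < 0) reac else prod
      xml2::xml_add_child(parent, "speciesReference",
                          species = paste0("M_", sbml_sid(met)),
                          stoichiometry = format(abs(st[[met]])),
                          constant = "true")
    }
    gpr_genes <- strsplit(r$gpr, " or ", fixed = TRUE)[[1]]
    gpr_genes <- gpr_genes[nzchar(gpr_genes)]
    if (length(gpr_genes)) {
      assoc <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      parent <- if (length(gpr_genes) > 1L)
        xml2::xml_add_child(assoc, "fbc:or") else assoc
      for (g in gpr_genes) {
        xml2::xml_add_child(parent, "fbc:geneProductRef",
                            "fbc:geneProduct" = paste0("G_", sbml_sid(g)))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

add_cv_term <- function(node, kind, kegg_id) {
  collection <- switch(kind,
                       compound = if (is_glycan_id(kegg_id)) "kegg.glycan" else "kegg.compound",
                       reaction = "kegg.reaction")
  ann <- xml2::xml_add_child(node, "annotation")
  rdf <- xml2::xml_add_child(ann, "rdf:RDF")
  desc <- xml2::xml_add_child(rdf, "rdf:Description")
  isnode <- xml2::xml_add_child(desc, "bqbiol:is")
  bag <- xml2::xml_add_child(isnode, "rdf:Bag")
  xml2::xml_add_child(bag, "rdf:li",
                      "rdf:resource" = sprintf("https://identifiers.org/%s:%s",
                                               collection, kegg_id))
  invisible(node)
}

#' Structural validation of an exported SBML file
#'
#' Checks that the file is well-formed XML in the SBML L3V1 core
#' namespace with the fbc extension declared, that every SId is valid,
#' that all species/compartment/gene-product references resolve, and
#' that every reaction has at least one reactant and one product and is
#' reversible with declared bounds.
#'
#' @param path path to an SBML file written by [write_sbml()].
#' @return `TRUE` invisibly; problems raise an error describing them.
#' @export
validate_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  fail <- function(...) stop(sprintf(...), call. = FALSE)
  if (!identical(xml2::xml_name(doc), "sbml")) fail("root element is not <sbml>")
  nsmap <- xml2::xml_ns(doc)
  if (!"http://www.sbml.org/sbml/level3/version1/core" %in% nsmap)
    fail("SBML L3V1 core namespace missing")
  if (!any(grepl("fbc", nsmap))) fail("fbc namespace missing")
  sid_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)

  comp_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//sbml:compartment", ns), "id")
  sp_nodes <- xml2::xml_find_all(doc, ".//sbml:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  gp_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//fbc:geneProduct", ns), "id")
  param_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//sbml:parameter", ns), "id")
  all_ids <- c(comp_ids, sp_ids, gp_ids, param_ids)
  if (!all(sid_ok(all_ids))) fail("invalid SId: %s", all_ids[!sid_ok(all_ids)][1])
  if (anyDuplicated(sp_ids)) fail("duplicate species id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  if (!all(sp_comp %in% comp_ids)) fail("species references unknown compartment")

  rxn_nodes <- xml2::xml_find_all(doc, ".//sbml:reaction", ns)
  for (rx in rxn_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    if (!sid_ok(rid)) fail("invalid reaction SId: %s", rid)
    if (!identical(xml2::xml_attr(rx, "reversible"), "true"))
      fail("reaction %s is not reversible", rid)
    for (b in c("lowerFluxBound", "upperFluxBound")) {
      bound <- xml2::xml_attr(rx, b)
      if (is.na(bound) || !bound %in% param_ids)
        fail("reaction %s has unresolved flux bound", rid)
    }
    refs <- xml2::xml_attr(
      xml2::xml_find_all(rx, ".//sbml:speciesReference", ns), "species")
    if (!all(refs %in% sp_ids)) fail("reaction %s references unknown species", rid)
    n_reac <- length(xml2::xml_find_all(rx, "./sbml:listOfReactants/sbml:speciesReference", ns))
    n_prod <- length(xml2::xml_find_all(rx, "./sbml:listOfProducts/sbml:speciesReference", ns))
    if (n_reac < 1L || n_prod < 1L)
      fail("reaction %s lacks reactants or products", rid)
    gprefs <- xml2::xml_attr(
      xml2::xml_find_all(rx, ".//fbc:geneProductRef", ns), "geneProduct")
    if (!all(gprefs %in% gp_ids)) fail("reaction %s references unknown gene product", rid)
  }
  invisible(TRUE)
}
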