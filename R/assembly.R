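#' Draft metabolic reconstruction container
#'
#' A `draft_model` holds the metabolites, reactions, compartments and
#' sparse stoichiometric matrix of a first-draft reconstruction.  All
#' reactions are reversible (KEGG annotation carries no directionality)
#' with symmetric default flux bounds of +/-1000; every metabolite sits
#' in a single default "cytosol" compartment except in community models,
#' where each query organism becomes its own compartment.  Gene-protein-
#' reaction rules are purely OR-joined since KEGG does not specify how
#' gene products interact.
#'
#' @section Fields:
#' * `model_id`, `kind` (`"single"`, `"consolidated"` or `"community"`)
#' * `metabolites`: data.frame with `model_id`, `kegg_id`, `name`,
#'   `formula`, `compartment`
#' * `reactions`: data.frame with `model_id`, `kegg_id`, `name`,
#'   `equation`, `gpr`, `rxn_attention`, `lower_bound`, `upper_bound`,
#'   `reversible`, plus a list-column `stoichiometry` (named numeric,
#'   negative = consumed) and a list-column `annotations`
#' * `compartments`: named character vector id -> label
#' * `S`: sparse `Matrix` metabolites x reactions
#' * `provenance`: list with `organisms` and `source`
#'
#' @name draft_model
NULL

DEFAULT_BOUND <- 1000

new_draft_model <- function(model_id, kind, metabolites, reactions,
                            compartments, provenance) {
  metabolites <- metabolites[order(metabolites$model_id), , drop = FALSE]
  rownames(metabolites) <- NULL
  ord <- order(reactions$model_id)
  reactions <- reactions[ord, , drop = FALSE]
  rownames(reactions) <- NULL
  reactions$stoichiometry <- unname(reactions$stoichiometry)
  if (!is.null(reactions$annotations))
    reactions$annotations <- unname(reactions$annotations)
  triplets <- lapply(seq_len(nrow(reactions)), function(j) {
    st <- reactions$stoichiometry[[j]]
    cbind(i = match(names(st), metabolites$model_id), j = j, x = as.numeric(st))
  })
  triplets <- do.call(rbind, c(triplets, list(cbind(i = integer(0), j = integer(0),
                                                    x = numeric(0)))))
  if (anyNA(triplets[, "i"]))
    stop("stoichiometry references a metabolite missing from the model")
  S <- Matrix::sparseMatrix(
    i = triplets[, "i"], j = triplets[, "j"], x = triplets[, "x"],
    dims = c(nrow(metabolites), nrow(reactions)),
    dimnames = list(metabolites$model_id, reactions$model_id))
  structure(list(model_id = model_id, kind = kind,
                 metabolites = metabolites, reactions = reactions,
                 compartments = compartments, S = S,
                 provenance = provenance),
            class = "draft_model")
}

#' @export
print.draft_model <- function(x, ...) {
  cat(sprintf("<draft_model> %s (%s): %d reactions, %d metabolites, %d compartment(s)\n",
              x$model_id, x$kind, nrow(x$reactions), nrow(x$metabolites),
              length(x$compartments)))
  invisible(x)
}

#' @export
summary.draft_model <- function(object, ...) {
  stats <- network_stats(object)
  cat(sprintf("Draft reconstruction '%s' (%s)\n", object$model_id, object$kind))
  cat(sprintf("  reactions: %d   metabolites: %d   compartments: %d\n",
              nrow(object$reactions), nrow(object$metabolites),
              length(object$compartments)))
  cat(sprintf("  giant component: %d reactions (%.2f%%)\n",
              stats$giant_reaction_count, stats$giant_reaction_fraction))
  cat(sprintf("  mean degree: %.3f   mean shortest path: %.3f\n",
              stats$mean_degree, stats$mean_shortest_path))
  cat(sprintf("  blocked metabolites: %d   same-sign metabolites: %d\n",
              stats$blocked_metabolites, stats$same_sign_metabolites))
  attention <- sum(nzchar(object$reactions$rxn_attention))
  if (attention) cat(sprintf("  reactions flagged for attention: %d\n", attention))
  invisible(stats)
}

# signed stoichiometry of a reaction record, collapsing repeats;
# a species on both sides would cancel, but ill-defined equations are
# filtered before assembly
record_stoichiometry <- function(record) {
  st <- c(stats::setNames(-record$substrates$coefficient, record$substrates$id),
          stats::setNames(record$products$coefficient, record$products$id))
  agg <- tapply(st, names(st), sum)[unique(names(st))]
  stats::setNames(as.numeric(agg), names(agg))
}

# model reaction set implied by an omission report: surviving records,
# with compound-ID alternatives standing in for replaced glycan reactions
select_model_reactions <- function(report, records, universe = records) {
  chosen <- list()     # reaction id -> record + gene-source reaction ids
  for (v in report$verdicts) {
    if (!v$status %in% c("kept", "kept_with_attention")) next
    if (identical(v$category, "glycan_replaced")) next
    chosen[[v$reaction]] <- list(record = records[[v$reaction]],
                                 gene_sources = v$reaction,
                                 attention = v$attention_text)
  }
  # replaced glycan reactions contribute their gene links to the alternative
  for (v in report$verdicts) {
    if (!identical(v$category, "glycan_replaced")) next
    rep_id <- v$replacement
    own <- report$verdicts[[rep_id]]
    if (!is.null(own) && own$status == "omitted") next  # alternative itself filtered
    if (is.null(chosen[[rep_id]])) {
      rec <- universe[[rep_id]]
      if (is.null(rec))
        stop(sprintf("replacement reaction %s not found in universe", rep_id))
      chosen[[rep_id]] <- list(record = rec, gene_sources = character(0),
                               attention = v$attention_text)
    }
    chosen[[rep_id]]$gene_sources <- union(chosen[[rep_id]]$gene_sources, v$reaction)
  }
  chosen[order(names(chosen))]
}

#' Build the consolidated draft reconstruction
#'
#' The consolidated model is the union of the kept reactions across all
#' query organisms, with one copy of each reaction whose GPR joins every
#' owning organism's genes with "or".  Replaced glycan reactions enter
#' through their compound-ID alternative; kept-with-attention reactions
#' carry their `rxn_attention` text into the model.  Full KEGG
#' annotation (names, formulas, IDs, raw records) is carried over.
#'
#' @param report an [apply_filters()] result.
#' @param records named list of the filtered `kegg_reaction` records.
#' @param matrices an [build_or_matrix()] result for the query organisms.
#' @param compounds named list of `kegg_compound` records.
#' @param universe reaction universe to resolve glycan replacements in;
#'   defaults to `records`.
#' @param model_id identifier for the model.
#' @return a [draft_model].
#' @export
build_consolidated <- function(report, records, matrices, compounds,
                               universe = records,
                               model_id = "consolidated") {
  chosen <- select_model_reactions(report, records, universe)
  rxn_rows <- list()
  met_ids <- character(0)
  for (id in names(chosen)) {
    entry <- chosen[[id]]
    rec <- entry$record
    genes <- sort(unique(unlist(lapply(entry$gene_sources, function(src)
      unlist(lapply(matrices$organisms, genes_for, matrices = matrices,
                    reaction = src))))))
    st <- record_stoichiometry(rec)
    met_ids <- union(met_ids, names(st))
    rxn_rows[[id]] <- list(
      model_id = id, kegg_id = rec$id, name = rec$name,
      equation = rec$equation_text,
      gpr = paste(genes, collapse = " or "),
      rxn_attention = entry$attention %||% "",
      lower_bound = -DEFAULT_BOUND, upper_bound = DEFAULT_BOUND,
      reversible = TRUE,
      stoichiometry = st,
      annotations = list(kegg_reaction = rec$id,
                         ec_numbers = rec$ec_numbers,
                         gene_sources = entry$gene_sources,
                         raw_text = rec$raw_text))
  }
  reactions <- data.frame(
    model_id = vapply(rxn_rows, `[[`, "", "model_id"),
    kegg_id = vapply(rxn_rows, `[[`, "", "kegg_id"),
    name = vapply(rxn_rows, `[[`, "", "name"),
    equation = vapply(rxn_rows, `[[`, "", "equation"),
    gpr = vapply(rxn_rows, `[[`, "", "gpr"),
    rxn_attention = vapply(rxn_rows, `[[`, "", "rxn_attention"),
    lower_bound = vapply(rxn_rows, `[[`, 0, "lower_bound"),
    upper_bound = vapply(rxn_rows, `[[`, 0, "upper_bound"),
    reversible = vapply(rxn_rows, `[[`, TRUE, "reversible"),
    stringsAsFactors = FALSE)
  reactions$stoichiometry <- lapply(rxn_rows, `[[`, "stoichiometry")
  reactions$annotations <- lapply(rxn_rows, `[[`, "annotations")

  met_ids <- sort(met_ids)
  unresolved <- setdiff(met_ids, names(compounds))
  if (length(unresolved))
    stop(sprintf("model references compounds missing from the compound map: %s",
                 paste(utils::head(unresolved, 5), collapse = ", ")))
  metabolites <- data.frame(
    model_id = met_ids,
    kegg_id = met_ids,
    name = vapply(met_ids, function(i) compounds[[i]]$name, ""),
    formula = vapply(met_ids, function(i) compounds[[i]]$formula, ""),
    compartment = "c",
    stringsAsFactors = FALSE)

  new_draft_model(model_id, "consolidated", metabolites, reactions,
                  compartments = c(c = "cytosol"),
                  provenance = list(organisms = matrices$organisms,
                                    source = "KEGG"))
}

#' Restrict the consolidated draft to one organism
#'
#' A single-organism draft is a copy of the consolidated model with
#' every reaction the organism does not own removed, GPRs restricted to
#' that organism's genes, and metabolites orphaned by the restriction
#' dropped.
#'
#' @param consolidated the [build_consolidated()] result.
#' @param matrices an [build_or_matrix()] result.
#' @param organism one of the query organism codes.
#' @return a [draft_model] of kind `"single"`.
#' @export
build_single <- function(consolidated, matrices, organism) {
  if (!organism %in% matrices$organisms)
    stop(sprintf("organism '%s' is not in the query list", organism))
  keep <- logical(nrow(consolidated$reactions))
  gprs <- character(nrow(consolidated$reactions))
  for (j in seq_len(nrow(consolidated$reactions))) {
    sources <- consolidated$reactions$annotations[[j]]$gene_sources
    genes <- sort(unique(unlist(lapply(sources, genes_for,
                                       matrices = matrices, organism = organism))))
    owned <- any(vapply(sources, function(src)
      src %in% colnames(matrices$or_matrix) &&
        matrices$or_matrix[organism, src] == 1L, TRUE))
    keep[j] <- owned
    gprs[j] <- paste(genes, collapse = " or ")
  }
  if (!any(keep))
    warning(sprintf("organism '%s' owns no kept reaction; model is empty", organism))
  reactions <- consolidated$reactions[keep, , drop = FALSE]
  reactions$gpr <- gprs[keep]
  used_mets <- sort(unique(unlist(lapply(reactions$stoichiometry, names))))
  metabolites <- consolidated$metabolites[
    consolidated$metabolites$model_id %in% used_mets, , drop = FALSE]
  new_draft_model(organism, "single", metabolites, reactions,
                  compartments = consolidated$compartments,
                  provenance = list(organisms = organism,
                                    source = consolidated$provenance$source))
}

#' Merge single-organism drafts into a community draft
#'
#' Each organism becomes its own compartment: metabolite and reaction
#' IDs are suffixed with `_<organism>`, so the compartments share
#' nothing (a first-draft community model contains no transport
#' reactions and the organisms are therefore disconnected).  Stripping
#' the suffix recovers the single models exactly.
#'
#' @param singles list of `draft_model`s of kind `"single"` with
#'   distinct organism IDs.
#' @param model_id identifier for the community model.
#' @return a [draft_model] of kind `"community"`.
#' @export
build_community <- function(singles, model_id = "community") {
  stopifnot(length(singles) >= 2L)
  orgs <- vapply(singles, `[[`, "", "model_id")
  if (anyDuplicated(orgs))
    stop("build_community: duplicate organism IDs in singles")
  met_list <- list()
  rxn_list <- list()
  for (m in singles) {
    org <- m$model_id
    mets <- m$metabolites
    mets$model_id <- paste0(mets$model_id, "_", org)
    mets$compartment <- org
    rxns <- m$reactions
    rxns$model_id <- paste0(rxns$model_id, "_", org)
    rxns$stoichiometry <- lapply(rxns$stoichiometry, function(st)
      stats::setNames(st, paste0(names(st), "_", org)))
    met_list[[org]] <- mets
    rxn_list[[org]] <- rxns
  }
  metabolites <- do.call(rbind, met_list)
  reactions <- do.call(rbind, rxn_list)
  new_draft_model(model_id, "community", metabolites, reactions,
                  compartments = stats::setNames(orgs, orgs),
                  provenance = list(organisms = orgs,
                                    source = singles[[1]]$provenance$source))
}

#' Split a community draft back into its single-organism drafts
#'
#' Inverse of [build_community()]: strips the `_<organism>` suffix from
#' metabolite and reaction IDs per compartment.
#'
#' @param community a [draft_model] of kind `"community"`.
#' @return named list of `draft_model`s of kind `"single"`.
#' @export
split_community <- function(community) {
  stopifnot(identical(community$kind, "community"))
  out <- list()
  for (org in names(community$compartments)) {
    suffix <- paste0("_", org)
    strip <- function(x) sub(paste0(suffix, "$"), "", x)
    mets <- community$metabolites[community$metabolites$compartment == org, ,
                                  drop = FALSE]
    mets$model_id <- strip(mets$model_id)
    mets$compartment <- "c"
    sel <- endsWith(community$reactions$model_id, suffix)
    rxns <- community$reactions[sel, , drop = FALSE]
    rxns$model_id <- strip(rxns$model_id)
    rxns$stoichiometry <- lapply(rxns$stoichiometry, function(st)
      stats::setNames(st, strip(names(st))))
    out[[org]] <- new_draft_model(org, "single", mets, rxns,
                                  compartments = c(c = "cytosol"),
                                  provenance = list(organisms = org,
                                                    source = community$provenance$source))
  }
  out
}
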