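#' Network statistics of a draft reconstruction
#'
#' The statistics are computed on the bipartite metabolite-reaction
#' graph implied by the stoichiometric matrix: one node per metabolite,
#' one per reaction, an edge wherever the S-matrix entry is nonzero
#' (coefficients do not weight the graph).  This is the graph the
#' organism-reactome incidence describes, and the one the connectivity
#' summaries refer to.
#'
#' @name reporting
NULL

# bipartite igraph of a model; metabolite nodes carry type TRUE
model_graph <- function(model) {
  S <- model$S
  idx <- Matrix::which(S != 0, arr.ind = TRUE)
  mets <- rownames(S)
  rxns <- colnames(S)
  g <- igraph::make_empty_graph(n = length(mets) + length(rxns), directed = FALSE)
  igraph::V(g)$name <- c(mets, rxns)
  igraph::V(g)$type <- c(rep(TRUE, length(mets)), rep(FALSE, length(rxns)))
  if (nrow(idx)) {
    edges <- rbind(mets[idx[, 1]], rxns[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(edges))
  }
  g
}

#' Connected components of the metabolite-reaction graph
#'
#' Components are reported largest-first by reaction count (ties broken
#' by metabolite count, then by lexicographically smallest member); the
#' giant component is the first.
#'
#' @param model a [draft_model].
#' @return a list with `membership` (named component index per node),
#'   `components` (list of node-name vectors, sorted as above) and
#'   `sizes` (data.frame with `metabolites`, `reactions` per component).
#' @export
connected_components <- function(model) {
  if (nrow(model$reactions) == 0L)
    return(list(membership = integer(0), components = list(),
                sizes = data.frame(metabolites = integer(0),
                                   reactions = integer(0))))
  g <- model_graph(model)
  comp <- igraph::components(g)
  nodes <- igraph::V(g)$name
  is_met <- igraph::V(g)$type
  members <- split(nodes, comp$membership)
  n_rxn <- vapply(split(!is_met, comp$membership), sum, 0L)
  n_met <- vapply(split(is_met, comp$membership), sum, 0L)
  first_member <- vapply(members, function(m) sort(m)[1], "")
  ord <- order(-n_rxn, -n_met, first_member)
  components <- lapply(members[ord], sort)
  membership <- stats::setNames(match(comp$membership, as.integer(names(members)[ord])),
                                nodes)
  list(membership = membership,
       components = unname(components),
       sizes = data.frame(metabolites = as.integer(n_met[ord]),
                          reactions = as.integer(n_rxn[ord])))
}

#' Mean degree of the metabolite-reaction graph
#'
#' `2 * |edges| / (n_metabolites + n_reactions)`, where an edge is a
#' nonzero S-matrix entry (a coefficient of 2 still contributes one
#' edge).
#'
#' @param model a [draft_model].
#' @return a number.
#' @export
mean_degree <- function(model) {
  n_nodes <- nrow(model$S) + ncol(model$S)
  if (n_nodes == 0L) return(NaN)
  2 * Matrix::nnzero(model$S) / n_nodes
}

#' Mean shortest path of the metabolite-reaction graph
#'
#' Average geodesic length over all unordered node pairs lying in the
#' same connected component; pairs in different components are excluded
#' rather than assigned infinite distance.
#'
#' @param model a [draft_model].
#' @return a number (`NaN` when no connected pair exists).
#' @export
mean_shortest_path <- function(model) {
  g <- model_graph(model)
  d <- igraph::distances(g)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) return(NaN)
  mean(vals)
}

#' Blocked and same-sign metabolites
#'
#' With transport reactions absent by construction, a blocked metabolite
#' is one occurring in exactly one reaction (a dead end), and a
#' same-sign metabolite occurs in exactly two reactions with
#' equal-signed stoichiometric entries (produced twice or consumed
#' twice, hence unbalanceable at steady state).  Together they bound the
#' set of potentially blocked metabolites.
#'
#' @param model a [draft_model].
#' @return list with integer fields `blocked` and `same_sign`.
#' @export
blocked_and_same_sign <- function(model) {
  S <- model$S
  occ <- Matrix::rowSums(S != 0)
  blocked <- sum(occ == 1)
  same_sign <- 0L
  for (i in which(occ == 2)) {
    vals <- S[i, ]
    vals <- vals[vals != 0]
    if (prod(sign(vals)) > 0) same_sign <- same_sign + 1L
  }
  list(blocked = as.integer(blocked), same_sign = as.integer(same_sign))
}

#' Full network-statistics summary
#'
#' @param model a [draft_model].
#' @return an object of class `network_stats` with `n_reactions`,
#'   `n_metabolites`, `component_sizes`, `giant_reaction_count`,
#'   `giant_reaction_fraction` (percent), `mean_degree`,
#'   `mean_shortest_path`, `blocked_metabolites`,
#'   `same_sign_metabolites`.
#' @export
network_stats <- function(model) {
  comp <- connected_components(model)
  giant <- if (nrow(comp$sizes)) comp$sizes$reactions[1] else 0L
  bs <- blocked_and_same_sign(model)
  structure(list(
    n_reactions = nrow(model$reactions),
    n_metabolites = nrow(model$metabolites),
    component_sizes = comp$sizes,
    giant_reaction_count = as.integer(giant),
    giant_reaction_fraction =
      if (nrow(model$reactions)) 100 * giant / nrow(model$reactions) else NaN,
    mean_degree = mean_degree(model),
    mean_shortest_path = mean_shortest_path(model),
    blocked_metabolites = bs$blocked,
    same_sign_metabolites = bs$same_sign
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("<network_stats> %d reactions / %d metabolites\n",
                     "  giant component: %d reactions (%.2f%%) of %d components\n",
                     "  mean degree %.3f, mean shortest path %.3f\n",
                     "  blocked %d, same-sign %d\n"),
              x$n_reactions, x$n_metabolites, x$giant_reaction_count,
              x$giant_reaction_fraction, nrow(x$component_sizes),
              x$mean_degree, x$mean_shortest_path,
              x$blocked_metabolites, x$same_sign_metabolites))
  invisible(x)
}

#' Reactions outside the giant component
#'
#' @param model a [draft_model].
#' @return character vector of reaction IDs sorted by their component's
#'   size (small components first) then ID.
#' @export
disconnected_reactions <- function(model) {
  comp <- connected_components(model)
  if (length(comp$components) <= 1L) return(character(0))
  out <- character(0)
  for (k in rev(seq_along(comp$components))[-length(comp$components)]) {
    members <- comp$components[[k]]
    out <- c(out, sort(members[members %in% model$reactions$model_id]))
  }
  out
}

#' Per-organism gene summaries
#'
#' For each query organism: the number of reactions with gene support,
#' the number of distinct genes mapped to reactions, and the
#' distribution of genes per reaction -- the tabular form of the
#' gene-plot/histogram outputs.
#'
#' @param matrices an [build_or_matrix()] result.
#' @return named list per organism with `n_reactions`, `n_genes`,
#'   `genes_per_reaction` (named integer vector per reaction) and
#'   `histogram` (table of genes-per-reaction counts).
#' @export
gene_histograms <- function(matrices) {
  out <- list()
  for (org in matrices$organisms) {
    gpr <- lengths(matrices$org_genes[[org]])
    out[[org]] <- list(
      n_reactions = length(gpr),
      n_genes = length(unique(unlist(matrices$org_genes[[org]]))),
      genes_per_reaction = gpr,
      histogram = table(factor(gpr)))
  }
  out
}

#' Render the omission accounting
#'
#' Totals, per-category counts, and the three percentages of the
#' omission report (reaction-level filtering over input, generic
#' compounds over evaluated compounds, all omissions over input), all
#' truncated to 2 decimals, as a printable character block and a named
#' list.
#'
#' @param report an [apply_filters()] result.
#' @return a list with `lines` (character vector) and `values` (named
#'   list of the totals and percentages).
#' @export
omission_summary <- function(report) {
  values <- list(
    total_input = report$total_input,
    reaction_filter_omitted =
      sum(report$category_counts[REACTION_FILTER_CATEGORIES]),
    remaining_after_reaction_filters =
      report$total_input - sum(report$category_counts[REACTION_FILTER_CATEGORIES]),
    massless_omitted = report$category_counts[["massless_compound"]],
    total_omitted = report$total_omitted,
    total_kept = report$total_kept,
    evaluated_compounds = length(report$evaluated_compounds),
    generic_compounds = length(report$generic_compounds),
    filter_percent = report$filter_percent,
    generic_compound_percent = report$generic_compound_percent,
    omitted_percent = report$omitted_percent)
  lines <- c(
    sprintf("Reactions in: %d", values$total_input),
    sprintf("Omitted by reaction filters: %d (%.2f%%)",
            values$reaction_filter_omitted, values$filter_percent),
    vapply(names(report$category_counts), function(cat_)
      sprintf("  %-20s %d", cat_, report$category_counts[[cat_]]), ""),
    sprintf("Remaining after reaction filters: %d",
            values$remaining_after_reaction_filters),
    sprintf("Generic (massless) compounds: %d of %d evaluated (%.2f%%)",
            values$generic_compounds, values$evaluated_compounds,
            values$generic_compound_percent),
    sprintf("Total omitted: %d (%.2f%%)", values$total_omitted,
            values$omitted_percent),
    sprintf("Kept in draft: %d", values$total_kept))
  list(lines = lines, values = values)
}

#' Omission accounting arithmetic
#'
#' The bookkeeping identities of the omission report, computed from the
#' raw counts: reactions omitted by the reaction-level screens leave
#' `total_input - reaction_filter_omitted` reactions whose compounds are
#' evaluated; reactions containing generic compounds raise the omission
#' total to `reaction_filter_omitted + massless_omitted`; the rest are
#' kept.  The three percentages (reaction-level filtering over input,
#' generic compounds over evaluated compounds, all omissions over
#' input) are truncated to 2 decimals.
#'
#' @param total_input number of reactions entering the filter.
#' @param reaction_filter_omitted omitted by the reaction-level screens.
#' @param massless_omitted omitted for containing a massless compound.
#' @param evaluated_compounds,generic_compounds compound counts from the
#'   compound-level screen.
#' @return named list with `remaining_after_reaction_filters`,
#'   `total_omitted`, `total_kept`, `filter_percent`,
#'   `generic_compound_percent`, `omitted_percent`.
#' @examples
#' omission_accounting(1745, 141, 378, 1626, 390)
#' @export
omission_accounting <- function(total_input, reaction_filter_omitted,
                                massless_omitted, evaluated_compounds,
                                generic_compounds) {
  total_omitted <- reaction_filter_omitted + massless_omitted
  list(
    remaining_after_reaction_filters = total_input - reaction_filter_omitted,
    total_omitted = total_omitted,
    total_kept = total_input - total_omitted,
    filter_percent = percent2(reaction_filter_omitted, total_input),
    generic_compound_percent = percent2(generic_compounds, evaluated_compounds),
    omitted_percent = percent2(total_omitted, total_input))
}

#' Write the network statistics as JSON and TSV
#'
#' @param stats a [network_stats()] result.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the list written as JSON.
#' @export
write_network_stats <- function(stats, json_path = NULL, tsv_path = NULL) {
  out <- list(
    n_reactions = stats$n_reactions,
    n_metabolites = stats$n_metabolites,
    giant_reaction_count = stats$giant_reaction_count,
    giant_reaction_fraction = stats$giant_reaction_fraction,
    mean_degree = stats$mean_degree,
    mean_shortest_path = stats$mean_shortest_path,
    blocked_metabolites = stats$blocked_metabolites,
    same_sign_metabolites = stats$same_sign_metabolites,
    component_sizes = stats$component_sizes)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  if (!is.null(tsv_path)) {
    df <- data.frame(metric = names(out)[1:8],
                     value = vapply(out[1:8], function(v) format(v), ""))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
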