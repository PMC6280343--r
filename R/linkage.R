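#' Build the Organisms-Reactions and Organisms-Reactions-Genes matrices
#'
#' Composes the per-organism gene-EC links with the EC-reaction links:
#' `or_matrix[o, r] = 1` iff some gene of organism `o` maps to an EC
#' number that maps to reaction `r`; the ORG extension records, for
#' every such cell, the sorted unique genes that support it.  The OR
#' matrix is the bipartite organism-reactome incidence the rest of the
#' pipeline is driven by.
#'
#' The reaction axis is the full reaction universe known to the run:
#' every reaction named in the EC-reaction table, whether or not any
#' query organism owns it (unowned reactions appear as all-zero
#' columns, and as empty rows in the ORG report).
#'
#' @param gene_ec named list of `link_table`s of kind `"gene-ec"`, one
#'   per query organism, names = organism codes.
#' @param ec_rxn a `link_table` of kind `"ec-reaction"`.
#' @return an object of class `org_matrices` with fields `organisms`,
#'   `reactions`, `or_matrix` (binary organisms x reactions),
#'   `org_genes` (nested list organism -> reaction -> character vector
#'   of genes), and `ec_reaction_matrix` (binary EC x reactions).
#' @examples
#' src <- kegg_source("local", root = k12_fixture())
#' ge <- lapply(stats::setNames(nm = c("eco", "ecj")),
#'              function(o) fetch_gene_ec_links(src, o))
#' ecs <- unique(unlist(lapply(ge, function(t) t$pairs$target)))
#' m <- build_or_matrix(ge, fetch_ec_reaction_links(src, ecs))
#' reaction_universe(m)
#' @export
build_or_matrix <- function(gene_ec, ec_rxn) {
  stopifnot(is.list(gene_ec), length(gene_ec) >= 1L,
            !is.null(names(gene_ec)), all(nzchar(names(gene_ec))))
  organisms <- names(gene_ec)
  ecs <- sort(unique(ec_rxn$pairs$source))
  reactions <- sort(unique(ec_rxn$pairs$target))
  ec_rxn_mat <- matrix(0L, length(ecs), length(reactions),
                       dimnames = list(ecs, reactions))
  ec_rxn_mat[cbind(match(ec_rxn$pairs$source, ecs),
                   match(ec_rxn$pairs$target, reactions))] <- 1L

  or_matrix <- matrix(0L, length(organisms), length(reactions),
                      dimnames = list(organisms, reactions))
  org_genes <- stats::setNames(vector("list", length(organisms)), organisms)
  for (org in organisms) {
    pairs <- gene_ec[[org]]$pairs
    foreign <- pairs$source[gene_organism(pairs$source) != org]
    if (length(foreign))
      stop(sprintf("build_or_matrix: gene '%s' does not belong to organism '%s'",
                   foreign[1], org))
    if (nrow(pairs) == 0L) {
      warning(sprintf("organism '%s' has no gene-EC links; its OR row is all zero", org))
      org_genes[[org]] <- list()
      next
    }
    genes_by_rxn <- list()
    pairs <- pairs[pairs$target %in% ecs, , drop = FALSE]
    if (nrow(pairs)) {
      # compose gene->EC with EC->reaction
      ec_to_rxns <- split(ec_rxn$pairs$target, ec_rxn$pairs$source)
      for (k in seq_len(nrow(pairs))) {
        for (r in ec_to_rxns[[pairs$target[k]]]) {
          genes_by_rxn[[r]] <- c(genes_by_rxn[[r]], pairs$source[k])
        }
      }
    }
    genes_by_rxn <- lapply(genes_by_rxn, function(g) sort(unique(g)))
    or_matrix[org, names(genes_by_rxn)] <- 1L
    org_genes[[org]] <- genes_by_rxn
  }
  structure(list(organisms = organisms, reactions = reactions,
                 or_matrix = or_matrix, org_genes = org_genes,
                 ec_reaction_matrix = ec_rxn_mat),
            class = "org_matrices")
}

#' @export
print.org_matrices <- function(x, ...) {
  cat(sprintf("<org_matrices> %d organisms x %d reactions (%d present in >=1 organism)\n",
              length(x$organisms), length(x$reactions),
              length(reaction_universe(x))))
  invisible(x)
}

# genes of (organism, reaction), character(0) when absent
genes_for <- function(matrices, organism, reaction) {
  g <- matrices$org_genes[[organism]][[reaction]]
  if (is.null(g)) character(0) else g
}

#' Summarize one ORG-report row
#'
#' For a reaction, reports the per-organism gene lists together with the
#' `Sum` of organisms whose metabolism contains the reaction, the
#' `Total` fraction of query organisms containing it, and the `Genes`
#' summary: the distinct per-organism gene counts in ascending order,
#' `";"`-joined (a single value when all organisms agree, `"0"` when no
#' organism has the reaction).
#'
#' @param matrices an [build_or_matrix()] result.
#' @param reaction a reaction ID present in the reaction universe axis.
#' @return an object of class `org_row` with fields `reaction`,
#'   `genes_by_organism`, `sum`, `total`, `genes_summary`.
#' @export
summarize_row <- function(matrices, reaction) {
  if (!reaction %in% matrices$reactions)
    stop(sprintf("summarize_row: unknown reaction ID '%s'", reaction))
  genes <- lapply(stats::setNames(nm = matrices$organisms),
                  function(o) genes_for(matrices, o, reaction))
  counts <- lengths(genes)
  s <- sum(counts > 0L)
  nonzero <- sort(unique(counts[counts > 0L]))
  structure(list(
    reaction = reaction,
    genes_by_organism = genes,
    sum = s,
    total = s / length(matrices$organisms),
    genes_summary = if (s == 0L) "0" else paste(nonzero, collapse = ";")
  ), class = "org_row")
}

#' @export
print.org_row <- function(x, ...) {
  cat(sprintf("<org_row> %s  Sum=%d Total=%s Genes=%s\n", x$reaction, x$sum,
              format(x$total), x$genes_summary))
  invisible(x)
}

#' Reactions present in at least one query organism
#'
#' The union reactome over the query list, sorted by KEGG ID: only for
#' these reactions are full records downloaded.
#'
#' @param matrices an [build_or_matrix()] result.
#' @return character vector of reaction IDs.
#' @export
reaction_universe <- function(matrices) {
  sort(colnames(matrices$or_matrix)[colSums(matrices$or_matrix) >= 1L])
}

#' Export the ORG report table
#'
#' One row per reaction in the full known reaction list (reactions
#' absent from every query organism render as `0/0/0` with empty gene
#' cells), columns: KEGG ID, a comma-joined gene-list column per
#' organism, Sum, Total, Genes.
#'
#' @param matrices an [build_or_matrix()] result.
#' @param path optional file path; when given, the table is written as
#'   tab-separated text with a header.
#' @return the report as a data.frame (invisibly when `path` is given).
#' @export
org_report <- function(matrices, path = NULL) {
  rows <- lapply(matrices$reactions, function(r) {
    row <- summarize_row(matrices, r)
    cells <- vapply(row$genes_by_organism, paste, "", collapse = ", ")
    c(`KEGG ID` = r, cells,
      Sum = as.character(row$sum),
      Total = format(row$total, trim = TRUE),
      Genes = if (row$sum == 0L) "0" else row$genes_summary)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
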