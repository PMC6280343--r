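#' KEGG identifier syntax
#'
#' KEGG uses disjoint, syntactically decidable identifier namespaces:
#' reactions (`R` + 5 digits), compounds (`C` + 5 digits), glycans
#' (`G` + 5 digits), organism codes (2-4 lowercase letters), Enzyme
#' Commission numbers (`a.b.c.d`, possibly with trailing dashes for
#' partially classified activities), and gene identifiers
#' (`org:locus`).  The category of an identifier is decidable from its
#' syntax alone, which is what makes downstream dispatch (e.g. glycan
#' vs compound handling in the filter rules) possible.
#'
#' @param x character vector of putative KEGG identifiers.
#' @return `kegg_id_type()` returns a character vector with elements in
#'   `c("reaction", "compound", "glycan", "organism", "ec", "gene",
#'   "unknown")`.  The `is_*_id()` predicates return logical vectors.
#' @examples
#' kegg_id_type(c("R00014", "C00001", "G00124", "eco", "1.2.1.-", "eco:b0507"))
#' @export
kegg_id_type <- function(x) {
  out <- rep("unknown", length(x))
  out[grepl("^R[0-9]{5}$", x)] <- "reaction"
  out[grepl("^C[0-9]{5}$", x)] <- "compound"
  out[grepl("^G[0-9]{5}$", x)] <- "glycan"
  out[grepl("^[a-z]{2,4}$", x)] <- "organism"
  out[grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$", x)] <- "ec"
  out[grepl("^[A-Za-z0-9]{2,5}:[A-Za-z0-9_.()-]+$", x)] <- "gene"
  out
}

#' @rdname kegg_id_type
#' @export
is_reaction_id <- function(x) grepl("^R[0-9]{5}$", x)

#' @rdname kegg_id_type
#' @export
is_compound_id <- function(x) grepl("^C[0-9]{5}$", x)

#' @rdname kegg_id_type
#' @export
is_glycan_id <- function(x) grepl("^G[0-9]{5}$", x)

#' @rdname kegg_id_type
#' @export
is_organism_code <- function(x) grepl("^[a-z]{2,4}$", x)

#' @rdname kegg_id_type
#' @export
is_ec_number <- function(x) grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$", x)

#' @rdname kegg_id_type
#' @export
is_gene_id <- function(x) grepl("^[A-Za-z0-9]{2,5}:[A-Za-z0-9_.()-]+$", x)

# participant of a reaction equation: compound or glycan
is_metabolite_id <- function(x) is_compound_id(x) | is_glycan_id(x)

# organism prefix of a gene id ("eco:b0507" -> "eco")
gene_organism <- function(x) sub(":.*$", "", x)

stop_kegg <- function(class, message, ...) {
  stop(structure(
    class = c(class, "keggrec_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
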