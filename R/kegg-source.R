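#' Define a KEGG data source
#'
#' A source is either the live KEGG REST service (`mode = "rest"`) or a
#' local directory of flat files in the same layout the cache uses
#' (`mode = "local"`): `links/<org>_ec.tsv` and `links/ec_rxn.tsv` as
#' two-column tab-separated tables, and one `records/<ID>.txt` flat-file
#' record per reaction/compound/glycan.  Every fetched record is written
#' to `cache_dir` before being returned, so a REST run followed by a
#' local run over the populated cache reproduces identical results, and
#' local mode never touches the network.
#'
#' @param mode `"local"` or `"rest"`.
#' @param root directory (local mode) or base URL (rest mode; defaults
#'   to the public KEGG REST endpoint).
#' @param cache_dir directory for the write-through cache; defaults to a
#'   per-session temporary directory.
#' @param batch_size maximum IDs per multi-entry `get` call in rest mode
#'   (the service documents a limit of 10).
#' @param max_attempts,backoff retry policy for rest fetches: number of
#'   attempts and base seconds between them.
#' @return an object of class `kegg_source`.
#' @examples
#' src <- kegg_source("local", root = k12_fixture())
#' fetch_gene_ec_links(src, "eco")
#' @export
kegg_source <- function(mode = c("local", "rest"), root = NULL,
                        cache_dir = NULL, batch_size = 10L,
                        max_attempts = 3L, backoff = 1) {
  mode <- match.arg(mode)
  if (mode == "rest" && is.null(root)) root <- "https://rest.kegg.jp"
  if (mode == "local") {
    if (is.null(root)) stop("local mode requires a root directory")
    root <- normalizePath(root, mustWork = TRUE)
  }
  if (is.null(cache_dir)) cache_dir <- file.path(tempdir(), "keggrec-cache")
  dir.create(file.path(cache_dir, "records"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cache_dir, "links"), recursive = TRUE, showWarnings = FALSE)
  stopifnot(batch_size >= 1L)
  structure(list(mode = mode, root = root, cache_dir = cache_dir,
                 batch_size = as.integer(batch_size),
                 max_attempts = as.integer(max_attempts), backoff = backoff),
            class = "kegg_source")
}

#' @export
print.kegg_source <- function(x, ...) {
  cat(sprintf("<kegg_source> mode=%s root=%s cache=%s\n", x$mode, x$root, x$cache_dir))
  invisible(x)
}

rest_get_lines <- function(source, path) {
  url <- paste0(source$root, "/", path)
  for (attempt in seq_len(source$max_attempts)) {
    res <- tryCatch(readLines(url, warn = FALSE), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (attempt < source$max_attempts) Sys.sleep(source$backoff * attempt)
  }
  stop_kegg("source-unavailable",
            sprintf("KEGG source unavailable after %d attempts: %s",
                    source$max_attempts, url))
}

read_link_tsv <- function(path) {
  if (!file.exists(path)) return(NULL)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", col.names = c("source", "target"))
  tab
}

write_link_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

new_link_table <- function(source_ids, target_ids, kind) {
  tab <- data.frame(source = as.character(source_ids),
                    target = as.character(target_ids),
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  tab <- tab[order(tab$source, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(pairs = tab, kind = kind), class = "link_table")
}

#' @export
print.link_table <- function(x, ...) {
  cat(sprintf("<link_table> kind=%s pairs=%d\n", x$kind, nrow(x$pairs)))
  invisible(x)
}

#' Fetch gene-to-EC links for one organism
#'
#' Step (1) of the pipeline: every association between a gene of the
#' query organism and an Enzyme Commission number, as annotated in
#' KEGG.  Pairs are deduplicated and sorted by gene then EC.
#'
#' @param source a [kegg_source()].
#' @param organism a KEGG organism code (e.g. `"eco"`).
#' @return a `link_table` of kind `"gene-ec"` whose `pairs` data.frame
#'   has columns `source` (gene `org:locus`) and `target` (EC number).
#' @export
fetch_gene_ec_links <- function(source, organism) {
  if (!is_organism_code(organism))
    stop_kegg("organism-not-found",
              sprintf("'%s' is not a valid KEGG organism code", organism))
  cache_file <- file.path(source$cache_dir, "links", paste0(organism, "_ec.tsv"))
  tab <- read_link_tsv(cache_file)
  if (is.null(tab)) {
    if (source$mode == "local") {
      tab <- read_link_tsv(file.path(source$root, "links", paste0(organism, "_ec.tsv")))
      if (is.null(tab))
        stop_kegg("organism-not-found",
                  sprintf("organism '%s' not found in local source %s",
                          organism, source$root))
    } else {
      lines <- rest_get_lines(source, paste0("link/enzyme/", organism))
      lines <- lines[nzchar(lines)]
      if (length(lines) == 0L)
        stop_kegg("organism-not-found",
                  sprintf("organism '%s' has no gene-enzyme links in KEGG", organism))
      parts <- strsplit(lines, "\t", fixed = TRUE)
      tab <- data.frame(source = vapply(parts, `[`, "", 1L),
                        target = sub("^ec:", "", vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
    }
    write_link_tsv(tab, cache_file)
  }
  new_link_table(tab$source, tab$target, "gene-ec")
}

#' Fetch EC-to-reaction links
#'
#' Step (2): the reactions catalyzed by each queried EC number.  ECs
#' with no linked reactions simply contribute no pairs; partial ECs
#' (trailing dashes) are linked like full ones.
#'
#' @param source a [kegg_source()].
#' @param ec_numbers character vector of EC numbers (duplicates
#'   ignored), or `NULL` for the source's complete EC-reaction table --
#'   the full reaction list known to a run, which is what the ORG
#'   report iterates so that reactions absent from every query organism
#'   still render as empty rows.
#' @return a `link_table` of kind `"ec-reaction"` restricted to the
#'   query ECs, sorted by EC then reaction.
#' @export
fetch_ec_reaction_links <- function(source, ec_numbers = NULL) {
  if (!is.null(ec_numbers)) {
    ec_numbers <- unique(as.character(ec_numbers))
    if (length(ec_numbers) == 0L)
      stop("fetch_ec_reaction_links: ec_numbers must be non-empty")
  }
  cache_file <- file.path(source$cache_dir, "links", "ec_rxn.tsv")
  tab <- read_link_tsv(cache_file)
  if (is.null(tab)) {
    if (source$mode == "local") {
      tab <- read_link_tsv(file.path(source$root, "links", "ec_rxn.tsv"))
      if (is.null(tab))
        stop_kegg("source-unavailable",
                  sprintf("no links/ec_rxn.tsv in local source %s", source$root))
    } else {
      lines <- rest_get_lines(source, "link/reaction/enzyme")
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      tab <- data.frame(source = sub("^ec:", "", vapply(parts, `[`, "", 1L)),
                        target = sub("^rn:", "", vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
    }
    write_link_tsv(tab, cache_file)
  }
  if (!is.null(ec_numbers))
    tab <- tab[tab$source %in% ec_numbers, , drop = FALSE]
  new_link_table(tab$source, tab$target, "ec-reaction")
}

#' Fetch and parse KEGG reaction/compound/glycan records
#'
#' Records are served from the write-through cache when present; in rest
#' mode misses are fetched in batches of at most `batch_size` IDs per
#' `get` call.  Output order matches input order.  IDs the source cannot
#' resolve are returned in `missing`, never silently dropped.
#'
#' @param source a [kegg_source()].
#' @param ids character vector of reaction (`R`), compound (`C`) or
#'   glycan (`G`) identifiers.
#' @return a list with `records` (named list of `kegg_reaction` /
#'   `kegg_compound` objects, in input order) and `missing` (character
#'   vector of unresolvable IDs).
#' @export
fetch_records <- function(source, ids) {
  ids <- as.character(ids)
  if (length(ids) == 0L) return(list(records = list(), missing = character(0)))
  bad <- ids[!(is_reaction_id(ids) | is_metabolite_id(ids))]
  if (length(bad))
    stop(sprintf("fetch_records: invalid KEGG IDs: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  uids <- unique(ids)
  cache_path <- function(id) file.path(source$cache_dir, "records", paste0(id, ".txt"))
  texts <- stats::setNames(vector("list", length(uids)), uids)
  for (id in uids) {
    p <- cache_path(id)
    if (file.exists(p)) texts[[id]] <- readChar(p, file.size(p))
  }
  todo <- uids[vapply(texts, is.null, TRUE)]
  if (length(todo)) {
    if (source$mode == "local") {
      for (id in todo) {
        p <- file.path(source$root, "records", paste0(id, ".txt"))
        if (file.exists(p)) texts[[id]] <- readChar(p, file.size(p))
      }
    } else {
      batches <- split(todo, ceiling(seq_along(todo) / source$batch_size))
      for (batch in batches) {
        lines <- rest_get_lines(source, paste0("get/", paste(batch, collapse = "+")))
        if (length(lines) == 0L) next
        entry_text <- split_kegg_entries(lines)
        for (id in names(entry_text)) texts[[id]] <- entry_text[[id]]
      }
    }
    for (id in todo) {
      if (!is.null(texts[[id]])) writeLines(texts[[id]], cache_path(id))
    }
    # cache round-trip so repeated fetches are byte-identical
    for (id in todo) {
      p <- cache_path(id)
      if (file.exists(p)) texts[[id]] <- readChar(p, file.size(p))
    }
  }
  missing <- uids[vapply(texts, is.null, TRUE)]
  records <- list()
  for (id in ids) {
    if (is.null(texts[[id]])) next
    records[[id]] <- if (is_reaction_id(id)) parse_reaction_record(texts[[id]])
                     else parse_compound_record(texts[[id]])
  }
  list(records = records, missing = missing)
}

# split a multi-entry flat-file response on /// terminators, keyed by ENTRY id
split_kegg_entries <- function(lines) {
  idx <- cumsum(c(1L, utils::head(grepl("^///", lines), -1L)))
  chunks <- split(lines, idx)
  out <- list()
  for (chunk in chunks) {
    chunk <- chunk[!grepl("^///", chunk)]
    if (!length(chunk)) next
    entry_line <- chunk[grepl("^ENTRY", chunk)]
    if (!length(entry_line)) next
    id <- strsplit(trimws(substring(entry_line[1], 13L)), "\\s+")[[1]][1]
    out[[id]] <- paste(c(chunk, "///"), collapse = "\n")
  }
  out
}
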