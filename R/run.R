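#' Configure a reconstruction run
#'
#' The runner mirrors the tool's invocation model: a list of organisms
#' plus optional flags.  An empty flag set builds the consolidated
#' reconstruction (the default).  The report-only flags `org_rxn_gen`,
#' `gene_plot` and `histogram` can run without any reconstruction, in
#' which case no reaction or compound records are downloaded at all;
#' `omitted_data` forces record download and filtering but builds no
#' model unless a build flag is also present.
#'
#' @param organisms character vector of KEGG organism codes (>= 1).
#' @param flags character vector drawn from `"consolidated"`,
#'   `"single"`, `"community"`, `"org_rxn_gen"`, `"gene_plot"`,
#'   `"histogram"`, `"omitted_data"`, `"disconnected_reactions"`.
#'   `"single_models"` and `"single_recs"` are accepted as aliases of
#'   `"single"`.
#' @param source a [kegg_source()].
#' @param out_dir run output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(organisms, flags = character(0),
                       source = kegg_source("rest"),
                       out_dir = tempfile("keggrec-run")) {
  organisms <- as.character(organisms)
  if (length(organisms) < 1L) stop("at least one organism is required", call. = FALSE)
  bad <- organisms[!is_organism_code(organisms)]
  if (length(bad))
    stop_kegg("usage-error",
              sprintf("invalid KEGG organism code(s): %s", paste(bad, collapse = ", ")))
  flags <- as.character(flags)
  flags[flags %in% c("single_models", "single_recs")] <- "single"
  known <- c("consolidated", "single", "community", "org_rxn_gen", "gene_plot",
             "histogram", "omitted_data", "disconnected_reactions")
  unknown <- setdiff(flags, known)
  if (length(unknown))
    stop_kegg("usage-error",
              sprintf("unknown flag(s): %s", paste(unknown, collapse = ", ")))
  if (length(flags) == 0L) flags <- "consolidated"
  structure(list(organisms = organisms, flags = unique(flags), source = source,
                 out_dir = out_dir), class = "run_config")
}

#' Execute a reconstruction run
#'
#' Runs only the stages the flags require: linkage (always), record
#' download and filtering (only when a model or the omission report is
#' requested), and model assembly per build flag.  All requested outputs
#' are written under `config$out_dir` along with a machine-readable
#' `manifest.json` (organisms, flags, stage counts).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`matrices`,
#'   and, when computed, `report`, `consolidated`, `singles`,
#'   `community`, `stats`) plus `out_dir`.
#' @export
run_reconstruction <- function(config) {
  stopifnot(inherits(config, "run_config"))
  flags <- config$flags
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  needs_records <- any(flags %in% c("consolidated", "single", "community",
                                    "omitted_data", "disconnected_reactions"))
  build_flags <- intersect(flags, c("consolidated", "single", "community"))
  log_msg <- function(...) message(sprintf(...))

  log_msg("[keggrec] linkage stage: %d organism(s)", length(config$organisms))
  gene_ec <- lapply(stats::setNames(nm = config$organisms),
                    function(org) fetch_gene_ec_links(config$source, org))
  ec_rxn <- fetch_ec_reaction_links(config$source)  # full known table
  matrices <- build_or_matrix(gene_ec, ec_rxn)
  universe <- reaction_universe(matrices)
  results <- list(matrices = matrices, out_dir = config$out_dir)

  if ("org_rxn_gen" %in% flags) {
    org_report(matrices, file.path(config$out_dir, "org_matrix.tsv"))
    log_msg("[keggrec] wrote ORG report (%d reactions)", length(matrices$reactions))
  }
  if (any(c("gene_plot", "histogram") %in% flags)) {
    hists <- gene_histograms(matrices)
    rows <- do.call(rbind, lapply(names(hists), function(org) {
      h <- hists[[org]]$histogram
      data.frame(organism = org, genes_per_reaction = names(h),
                 reactions = as.integer(h), stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, file.path(config$out_dir, "gene_histograms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$histograms <- hists
  }

  if (needs_records) {
    log_msg("[keggrec] fetching %d reaction records", length(universe))
    fetched <- fetch_records(config$source, universe)
    records <- fetched$records
    if (length(fetched$missing))
      warning(sprintf("unresolvable reaction IDs: %s",
                      paste(fetched$missing, collapse = ", ")))
    met_ids <- sort(unique(unlist(lapply(records, reaction_participants))))
    cmp_fetched <- fetch_records(config$source, met_ids)
    compounds <- cmp_fetched$records
    # pull in cross-referenced compound records for glycan translation
    xrefs <- stats::na.omit(vapply(compounds, `[[`, "", "same_as"))
    xrefs <- setdiff(unique(xrefs), names(compounds))
    if (length(xrefs)) {
      extra <- fetch_records(config$source, xrefs)
      compounds <- c(compounds, extra$records)
    }
    report <- apply_filters(records, compounds)
    results$report <- report
    if ("omitted_data" %in% flags) {
      write_omission_report(report,
                            json_path = file.path(config$out_dir, "omitted_data.json"),
                            tsv_path = file.path(config$out_dir, "omitted_data.tsv"))
      writeLines(omission_summary(report)$lines,
                 file.path(config$out_dir, "omission_summary.txt"))
    }

    if (length(build_flags) || "disconnected_reactions" %in% flags) {
      consolidated <- build_consolidated(report, records, matrices, compounds)
      results$consolidated <- consolidated
      if ("consolidated" %in% flags) {
        write_sbml(consolidated, file.path(config$out_dir, "consolidated.xml"))
        write_model_json(consolidated, file.path(config$out_dir, "consolidated.json"))
      }
      if (any(c("single", "community") %in% flags)) {
        singles <- lapply(stats::setNames(nm = config$organisms),
                          function(org) build_single(consolidated, matrices, org))
        results$singles <- singles
        if ("single" %in% flags) {
          for (org in names(singles)) {
            write_sbml(singles[[org]],
                       file.path(config$out_dir, sprintf("single_%s.xml", org)))
            write_model_json(singles[[org]],
                             file.path(config$out_dir, sprintf("single_%s.json", org)))
          }
        }
        if ("community" %in% flags && length(singles) >= 2L) {
          community <- build_community(unname(singles))
          results$community <- community
          write_sbml(community, file.path(config$out_dir, "community.xml"))
          write_model_json(community, file.path(config$out_dir, "community.json"))
        }
      }
      results$stats <- network_stats(consolidated)
      write_network_stats(results$stats,
                          json_path = file.path(config$out_dir, "network_stats.json"),
                          tsv_path = file.path(config$out_dir, "network_stats.tsv"))
      if ("disconnected_reactions" %in% flags) {
        writeLines(disconnected_reactions(consolidated),
                   file.path(config$out_dir, "disconnected_reactions.txt"))
      }
    }
  }

  manifest <- list(
    organisms = config$organisms,
    flags = flags,
    source_mode = config$source$mode,
    n_reactions_universe = length(universe),
    n_reactions_known = length(matrices$reactions),
    outputs = sort(list.files(config$out_dir)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("[keggrec] run complete: %s", config$out_dir)
  invisible(results)
}
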