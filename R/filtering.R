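#' Reaction and compound exclusion rules
#'
#' A first-draft reconstruction keeps only reactions that are usable in
#' steady-state constraint-based modeling.  Five reaction-level screens
#' run in a fixed first-match-wins order -- generic/general remark,
#' structural polymer equation, glycan handling (with translation to
#' compound-ID equivalents where cross-references allow), ill-defined
#' equation (same compound on both sides), comment-declared
#' polymerization -- followed by a compound-level screen that omits any
#' surviving reaction containing a massless (generic) compound.  Every
#' reaction receives exactly one verdict; kept-but-suspect reactions are
#' tagged through the `rxn_attention` annotation instead of being
#' silently retained.
#'
#' @name filtering
NULL

GENERIC_TRIGGERS <- c("generic", "general reaction", "general")

#' Generic/general reaction screen
#'
#' `TRUE` when the record's remark or comment field contains any of the
#' trigger strings "Generic", "General" or "General reaction"
#' (case-insensitive substring match).  Such records describe reaction
#' families, not concrete conversions.
#'
#' @param record a `kegg_reaction`.
#' @return logical flag.
#' @export
is_generic_comment <- function(record) {
  text <- tolower(paste(record$remark, record$comment))
  any(vapply(GENERIC_TRIGGERS, grepl, TRUE, x = text, fixed = TRUE))
}

#' Polymer-equation screen
#'
#' `TRUE` when the equation carries symbolic coefficients (`n`, `m`,
#' `(n+1)`, ...) -- polymerization or non-specific reactions that have no
#' fixed stoichiometry and hence no steady-state interpretation.
#' Numeric coefficients, and `n`/`m` letters inside identifiers, never
#' trigger.
#'
#' @param record a `kegg_reaction`.
#' @return logical flag.
#' @export
is_polymer <- function(record) {
  isTRUE(record$is_symbolic)
}

#' Comment-declared polymerization screen
#'
#' `TRUE` when the comment declares polymerization without the equation
#' being symbolic; such reactions are omitted as potential
#' polymerization reactions, a category distinct from the structural
#' polymer screen.
#'
#' @param record a `kegg_reaction`.
#' @return logical flag.
#' @export
is_possible_polymer <- function(record) {
  grepl("polymer", tolower(paste(record$comment, record$remark)), fixed = TRUE)
}

#' Ill-defined-equation screen
#'
#' `TRUE` when at least one metabolite ID occurs on both sides of the
#' equation: such a reaction carries no net conversion for that species
#' and is removed as ill-defined.
#'
#' @param record a `kegg_reaction`.
#' @return logical flag.
#' @export
is_ill_defined <- function(record) {
  length(intersect(record$substrates$id, record$products$id)) > 0L
}

#' Generic (massless) compound screen
#'
#' A compound is generic when none of its mass fields carries a positive
#' value: `exact_mass` and `mol_weight` for compounds, plus the
#' glycan-only `mass` field.  A stored mass of 0 encodes "generic" and
#' is preserved as such.  A glycan with only the `mass` field present
#' and positive is *not* generic: a specific mass is given, so the
#' compound is included.
#'
#' @param record a `kegg_compound`.
#' @return logical flag.
#' @export
is_generic_compound <- function(record) {
  masses <- c(record$exact_mass, record$mol_weight, record$mass)
  !any(masses > 0, na.rm = TRUE)
}

new_verdict <- function(reaction, status, category, attention_text = "",
                        replacement = NA_character_) {
  structure(list(reaction = reaction, status = status, category = category,
                 attention_text = attention_text, replacement = replacement),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("<filter_verdict> %s: %s (%s)%s\n", x$reaction, x$status, x$category,
              if (!is.na(x$replacement)) paste0(" -> ", x$replacement) else ""))
  if (nzchar(x$attention_text)) cat("  ", x$attention_text, "\n", sep = "")
  invisible(x)
}

# canonical orientation-insensitive key of an equation's participant multiset
equation_key <- function(substrate_ids, product_ids) {
  side <- function(ids) paste(sort(ids), collapse = "+")
  paste(sort(c(side(substrate_ids), side(product_ids))), collapse = "<=>")
}

#' Translate a glycan reaction to its compound-ID equivalent
#'
#' KEGG keeps carbohydrate structures in a separate glycan (`G`)
#' namespace; some glycans also exist as ordinary compounds (`C`)
#' through "Same as" cross-references.  When every glycan participant of
#' a reaction translates to a compound ID and a reaction with exactly
#' the translated participant multiset exists in the reaction universe,
#' that alternative replaces the glycan reaction in the draft
#' (`glycan_replaced`).  A reaction whose participants are all glycans
#' and which has no such alternative is omitted (`glycan_only_omitted`),
#' as is one whose translation exists but lands on a generic compound.
#' A mixed reaction with untranslatable glycans and no alternative is
#' kept with an attention mark (`glycan_kept_no_alternative`) for
#' curator review.
#'
#' @param record a `kegg_reaction` with at least one glycan participant.
#' @param compounds named list of `kegg_compound` records (the
#'   cross-reference source).
#' @param universe named list of `kegg_reaction` records to search for
#'   the compound-ID alternative (the global reaction universe).
#' @return a `filter_verdict`.
#' @export
translate_glycan_reaction <- function(record, compounds, universe) {
  parts <- reaction_participants(record)
  glycans <- parts[is_glycan_id(parts)]
  if (length(glycans) == 0L)
    stop("translate_glycan_reaction: no glycan participant in ", record$id)
  translate_one <- function(id) {
    if (!is_glycan_id(id)) return(id)
    rec <- compounds[[id]]
    if (is.null(rec) || is.na(rec$same_as) || !is_compound_id(rec$same_as))
      return(NA_character_)
    rec$same_as
  }
  trans_sub <- vapply(record$substrates$id, translate_one, "")
  trans_prod <- vapply(record$products$id, translate_one, "")
  fully_translated <- !anyNA(c(trans_sub, trans_prod))
  pure_glycan <- all(is_glycan_id(parts))

  alternative <- NA_character_
  if (fully_translated) {
    key <- equation_key(trans_sub, trans_prod)
    for (cand in universe) {
      if (identical(cand$id, record$id)) next
      if (any(is_glycan_id(reaction_participants(cand)))) next
      if (identical(equation_key(cand$substrates$id, cand$products$id), key)) {
        alternative <- cand$id
        break
      }
    }
  }

  if (!is.na(alternative)) {
    return(new_verdict(
      record$id, "kept", "glycan_replaced",
      attention_text = sprintf(
        "Glycan reaction: the compound-ID equivalent %s is used in the draft instead",
        alternative),
      replacement = alternative))
  }
  if (fully_translated) {
    translated <- unique(c(trans_sub, trans_prod))
    generic_hit <- vapply(translated, function(id) {
      rec <- compounds[[id]]
      !is.null(rec) && is_generic_compound(rec)
    }, TRUE)
    if (any(generic_hit)) {
      return(new_verdict(
        record$id, "omitted", "glycan_only_omitted",
        attention_text = sprintf(
          "Glycan reaction omitted: translated compound %s is generic",
          translated[generic_hit][1])))
    }
  }
  if (pure_glycan) {
    return(new_verdict(
      record$id, "omitted", "glycan_only_omitted",
      attention_text = "Reaction contains only glycans and has no compound-ID alternative"))
  }
  new_verdict(
    record$id, "kept_with_attention", "glycan_kept_no_alternative",
    attention_text = paste("Glycan-containing reaction kept for lack of an",
                           "alternative compound-ID reaction; inspect carefully"))
}

OMITTED_CATEGORIES <- c("generic_comment", "polymer", "glycan_only_omitted",
                        "ill_defined", "massless_compound", "possible_polymer")
REACTION_FILTER_CATEGORIES <- setdiff(OMITTED_CATEGORIES, "massless_compound")

# percentages are truncated (not rounded) to 2 decimals
percent2 <- function(count, denom) {
  if (denom == 0) return(0)
  trunc(round(100 * count / denom, 6) * 100) / 100
}

#' Apply all exclusion rules and build the omission report
#'
#' Runs the reaction-level screens in first-match-wins order
#' (generic remark, polymer equation, glycan handling, ill-defined
#' equation, comment-declared polymerization), then evaluates the
#' compounds of the surviving reactions and omits any reaction that
#' contains a generic (massless) compound.  Compounds missing from the
#' compound map are conservatively treated as massless and listed
#' separately.
#'
#' @param records named list of `kegg_reaction` records to filter.
#' @param compounds named list of `kegg_compound` records covering the
#'   reactions' participants.
#' @param universe named list of `kegg_reaction` records used when
#'   searching for compound-ID alternatives to glycan reactions;
#'   defaults to `records`.
#' @return an object of class `omission_report`: fields `verdicts`
#'   (list of `filter_verdict`, sorted by reaction ID),
#'   `category_counts`, `total_input`, `total_omitted`, `total_kept`,
#'   `evaluated_compounds`, `generic_compounds`,
#'   `unresolved_compounds`, and the percentages `filter_percent`
#'   (reaction-level omissions over input), `generic_compound_percent`
#'   (generic compounds over evaluated compounds) and `omitted_percent`
#'   (all omissions over input), each truncated to 2 decimals.
#' @export
apply_filters <- function(records, compounds, universe = records) {
  ids <- sort(vapply(records, `[[`, "", "id"))
  records <- records[match(ids, vapply(records, `[[`, "", "id"))]
  names(records) <- ids
  verdicts <- list()
  for (rec in records) {
    verdicts[[rec$id]] <-
      if (is_generic_comment(rec)) {
        new_verdict(rec$id, "omitted", "generic_comment",
                    "Remark/comment marks this as a generic or general reaction")
      } else if (is_polymer(rec)) {
        new_verdict(rec$id, "omitted", "polymer",
                    "Polymerization or non-specific reaction (symbolic n/m coefficient)")
      } else if (any(is_glycan_id(reaction_participants(rec)))) {
        translate_glycan_reaction(rec, compounds, universe)
      } else if (is_ill_defined(rec)) {
        new_verdict(rec$id, "omitted", "ill_defined",
                    "Ill-defined reaction: same compound on both sides of the equation")
      } else if (is_possible_polymer(rec)) {
        new_verdict(rec$id, "omitted", "possible_polymer",
                    "Comment indicates a potential polymerization reaction")
      } else {
        new_verdict(rec$id, "kept", "none")
      }
  }

  # compound-level screen over the reactions that survived; the equation of a
  # glycan_replaced original is not in the model, so its own participants are
  # screened when its replacement reaction is (that record has its own verdict)
  survivor <- vapply(verdicts, function(v)
    v$status %in% c("kept", "kept_with_attention") &&
      v$category != "glycan_replaced", TRUE)
  evaluated <- unique(unlist(lapply(records[survivor], reaction_participants)))
  evaluated <- sort(evaluated %||% character(0))
  resolvable <- evaluated[evaluated %in% names(compounds)]
  unresolved <- setdiff(evaluated, resolvable)
  if (length(unresolved))
    warning(sprintf("%d compound(s) not resolvable; treated as massless: %s",
                    length(unresolved),
                    paste(utils::head(unresolved, 5), collapse = ", ")))
  generic <- resolvable[vapply(resolvable, function(id)
    is_generic_compound(compounds[[id]]), TRUE)]
  massless <- c(generic, unresolved)
  for (id in names(verdicts)[survivor]) {
    hit <- intersect(reaction_participants(records[[id]]), massless)
    if (length(hit)) {
      verdicts[[id]] <- new_verdict(
        id, "omitted", "massless_compound",
        sprintf(paste("This reaction contains a generic compound or a compound",
                      "without mass in KEGG (%s)"), paste(hit, collapse = ", ")))
    }
  }

  statuses <- vapply(verdicts, `[[`, "", "status")
  categories <- vapply(verdicts, `[[`, "", "category")
  category_counts <- vapply(stats::setNames(nm = OMITTED_CATEGORIES),
                            function(cat) sum(categories == cat &
                                                statuses == "omitted"), 0L)
  total_input <- length(verdicts)
  filter_omitted <- sum(category_counts[REACTION_FILTER_CATEGORIES])
  acc <- omission_accounting(total_input, filter_omitted,
                             category_counts[["massless_compound"]],
                             length(evaluated), length(generic))

  structure(list(
    verdicts = verdicts,
    category_counts = category_counts,
    total_input = total_input,
    total_omitted = as.integer(acc$total_omitted),
    total_kept = as.integer(acc$total_kept),
    evaluated_compounds = evaluated,
    generic_compounds = generic,
    unresolved_compounds = unresolved,
    filter_percent = acc$filter_percent,
    generic_compound_percent = acc$generic_compound_percent,
    omitted_percent = acc$omitted_percent
  ), class = "omission_report")
}

#' @export
print.omission_report <- function(x, ...) {
  cat(sprintf("<omission_report> %d reactions: %d kept, %d omitted (%.2f%%)\n",
              x$total_input, x$total_kept, x$total_omitted, x$omitted_percent))
  for (cat_ in names(x$category_counts)) {
    if (x$category_counts[[cat_]] > 0)
      cat(sprintf("  %-20s %d\n", cat_, x$category_counts[[cat_]]))
  }
  cat(sprintf("  generic compounds: %d of %d evaluated (%.2f%%)\n",
              length(x$generic_compounds), length(x$evaluated_compounds),
              x$generic_compound_percent))
  invisible(x)
}

#' Export an omission report
#'
#' Writes the per-verdict records as structured JSON and a
#' human-readable TSV summary next to it.
#'
#' @param report an `omission_report`.
#' @param json_path,tsv_path output file paths (`NULL` to skip either).
#' @return invisibly, the list written as JSON.
#' @export
write_omission_report <- function(report, json_path = NULL, tsv_path = NULL) {
  verdict_rows <- lapply(report$verdicts, function(v)
    list(reaction = v$reaction, status = v$status, category = v$category,
         attention_text = v$attention_text,
         replacement = if (is.na(v$replacement)) NULL else v$replacement))
  out <- list(
    total_input = report$total_input,
    total_omitted = report$total_omitted,
    total_kept = report$total_kept,
    category_counts = as.list(report$category_counts),
    filter_percent = report$filter_percent,
    generic_compound_percent = report$generic_compound_percent,
    omitted_percent = report$omitted_percent,
    generic_compounds = report$generic_compounds,
    unresolved_compounds = report$unresolved_compounds,
    verdicts = unname(verdict_rows)
  )
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  if (!is.null(tsv_path)) {
    df <- data.frame(
      reaction = vapply(report$verdicts, `[[`, "", "reaction"),
      status = vapply(report$verdicts, `[[`, "", "status"),
      category = vapply(report$verdicts, `[[`, "", "category"),
      replacement = vapply(report$verdicts, `[[`, "", "replacement"),
      attention = vapply(report$verdicts, `[[`, "", "attention_text"),
      stringsAsFactors = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
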