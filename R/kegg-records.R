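#' Parse a KEGG flat-file record into its keyword fields
#'
#' KEGG text records are line-oriented: a keyword occupies the first 12
#' columns and its value continues on subsequent lines indented by 12
#' spaces, until the record terminator `///`.  This parser returns the
#' raw field texts; typed accessors ([parse_reaction_record()],
#' [parse_compound_record()]) build domain records on top of it.
#'
#' @param text a single string or character vector of lines holding one
#'   KEGG record.
#' @return named list mapping each keyword to its (newline-joined) value.
#' @export
parse_kegg_flat <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[!grepl("^///", lines)]
  fields <- list()
  key <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\S", ln)) {
      key <- trimws(substr(ln, 1L, 12L))
      val <- trimws(substring(ln, 13L))
      fields[[key]] <- c(fields[[key]], val)
    } else if (!is.null(key)) {
      fields[[key]] <- c(fields[[key]], trimws(ln))
    }
  }
  lapply(fields, paste, collapse = "\n")
}

#' Parse one side or term of a KEGG reaction equation
#'
#' Splits an equation on its reversible arrow (`<=>` or the typeset
#' double arrow) and each side on `+` separators.  Each term is
#' `[coefficient] ID`, where an omitted coefficient is 1.  Numeric
#' coefficients (integers or decimals) parse to numbers; symbolic
#' polymer coefficients such as `n`, `m`, `(n+1)`, `2n` are retained
#' verbatim and flag the equation as symbolic.  Participants are
#' classified as compound or glycan by their ID prefix.
#'
#' @param equation_text equation string, e.g.
#'   `"C06136 + C00001 <=> C06135 + C00124"`.
#' @return a list with components `substrates` and `products` (each a
#'   data.frame with columns `id`, `coefficient` (numeric, `NA` when
#'   symbolic) and `expression` (the verbatim coefficient text)), and a
#'   logical `is_symbolic`.
#' @examples
#' parse_equation("2 C00002 + (n+1) C00001 <=> C00008")
#' @export
parse_equation <- function(equation_text) {
  stopifnot(is.character(equation_text), length(equation_text) == 1L)
  arrow <- if (grepl("<=>", equation_text, fixed = TRUE)) "<=>" else
    if (grepl("⇔", equation_text)) "⇔" else
      stop_kegg("equation-parse-error",
                sprintf("no reversible arrow in equation: '%s'", equation_text),
                offending = equation_text)
  sides <- strsplit(equation_text, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop_kegg("equation-parse-error",
              sprintf("equation must have exactly one arrow: '%s'", equation_text),
              offending = equation_text)
  parse_side <- function(side) {
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L)
      stop_kegg("equation-parse-error",
                sprintf("empty equation side in '%s'", equation_text),
                offending = side)
    parsed <- lapply(terms, parse_equation_term, equation = equation_text)
    do.call(rbind, parsed)
  }
  substrates <- parse_side(sides[1])
  products <- parse_side(sides[2])
  list(
    substrates = substrates,
    products = products,
    is_symbolic = anyNA(substrates$coefficient) || anyNA(products$coefficient)
  )
}

# one "[coefficient] ID" term -> data.frame(id, coefficient, expression)
parse_equation_term <- function(term, equation) {
  m <- regmatches(term, regexec("^(?:(.*\\S)\\s+)?([CG][0-9]{5})$", term))[[1]]
  if (length(m) == 0L)
    stop_kegg("equation-parse-error",
              sprintf("malformed equation term '%s' in '%s'", term, equation),
              offending = term)
  expr <- m[2]
  id <- m[3]
  if (!nzchar(expr)) {
    coef <- 1
    expr <- "1"
  } else if (grepl("^[0-9]+(\\.[0-9]+)?$", expr)) {
    coef <- as.numeric(expr)
    if (coef <= 0)
      stop_kegg("equation-parse-error",
                sprintf("non-positive coefficient in term '%s'", term),
                offending = term)
  } else if (grepl("[nm]", expr)) {
    coef <- NA_real_  # symbolic polymer coefficient, kept verbatim
  } else {
    stop_kegg("equation-parse-error",
              sprintf("malformed coefficient '%s' in term '%s'", expr, term),
              offending = term)
  }
  data.frame(id = id, coefficient = coef, expression = expr,
             stringsAsFactors = FALSE)
}

#' Parse a KEGG reaction record
#'
#' @param text raw flat-file text of one reaction record.
#' @return an object of class `kegg_reaction`: a list with `id`, `name`,
#'   `equation_text`, `substrates`, `products` (see [parse_equation()]),
#'   `is_symbolic`, `ec_numbers`, `comment`, `remark`, `raw_text`.
#' @export
parse_reaction_record <- function(text) {
  raw <- paste(if (length(text) == 1L) text else paste(text, collapse = "\n"))
  f <- parse_kegg_flat(text)
  entry <- strsplit(trimws(f$ENTRY %||% ""), "\\s+")[[1]][1]
  if (is.na(entry) || !is_reaction_id(entry))
    stop_kegg("record-parse-error",
              sprintf("not a reaction record (ENTRY '%s')", entry %||% ""))
  if (is.null(f$EQUATION))
    stop_kegg("record-parse-error", sprintf("reaction %s has no EQUATION", entry))
  eqtext <- gsub("\n", " ", f$EQUATION)
  eq <- parse_equation(eqtext)
  ecs <- character(0)
  if (!is.null(f$ENZYME)) {
    ecs <- strsplit(gsub("\n", " ", f$ENZYME), "\\s+")[[1]]
    ecs <- ecs[nzchar(ecs)]
  }
  structure(list(
    id = entry,
    name = gsub("\n", " ", f$NAME %||% ""),
    equation_text = eqtext,
    substrates = eq$substrates,
    products = eq$products,
    is_symbolic = eq$is_symbolic,
    ec_numbers = ecs,
    comment = gsub("\n", " ", f$COMMENT %||% ""),
    remark = gsub("\n", " ", f$REMARK %||% ""),
    raw_text = raw
  ), class = "kegg_reaction")
}

#' Parse a KEGG compound or glycan record
#'
#' Compound records carry `EXACT_MASS` and `MOL_WEIGHT`; glycan records
#' carry only a `MASS` field (often composition-specific even when the
#' formula contains a residue symbol).  A `REMARK` line of the form
#' `Same as: G#####` (or `C#####` on a glycan record) is the
#' glycan-compound cross-reference and populates `same_as`.
#'
#' @param text raw flat-file text of one compound/glycan record.
#' @return an object of class `kegg_compound`: a list with `id`, `name`,
#'   `formula`, `exact_mass`, `mol_weight`, `mass` (each `NA` when
#'   absent), `same_as` (`NA` when absent), `remark`, `raw_text`.
#' @export
parse_compound_record <- function(text) {
  raw <- paste(if (length(text) == 1L) text else paste(text, collapse = "\n"))
  f <- parse_kegg_flat(text)
  entry <- strsplit(trimws(f$ENTRY %||% ""), "\\s+")[[1]][1]
  if (is.na(entry) || !(is_compound_id(entry) || is_glycan_id(entry)))
    stop_kegg("record-parse-error",
              sprintf("not a compound/glycan record (ENTRY '%s')", entry %||% ""))
  num_or_na <- function(v) {
    if (is.null(v)) return(NA_real_)
    x <- suppressWarnings(as.numeric(strsplit(trimws(v), "\\s+")[[1]][1]))
    if (is.na(x)) NA_real_ else x
  }
  remark <- gsub("\n", " ", f$REMARK %||% "")
  same_as <- NA_character_
  sm <- regmatches(remark, regexec("Same as:\\s*([CG][0-9]{5})", remark))[[1]]
  if (length(sm) == 2L) same_as <- sm[2]
  masses <- c(exact_mass = num_or_na(f$EXACT_MASS),
              mol_weight = num_or_na(f$MOL_WEIGHT),
              mass = num_or_na(f$MASS))
  if (any(masses < 0, na.rm = TRUE))
    stop_kegg("record-parse-error",
              sprintf("negative mass in record %s", entry))
  name <- gsub("\n", " ", f$NAME %||% "")
  name <- sub(";$", "", strsplit(name, ";")[[1]][1] %||% "")
  structure(list(
    id = entry,
    name = if (is.na(name)) "" else trimws(name),
    formula = trimws(gsub("\n", " ", f$FORMULA %||% "")),
    exact_mass = masses[["exact_mass"]],
    mol_weight = masses[["mol_weight"]],
    mass = masses[["mass"]],
    same_as = same_as,
    remark = remark,
    raw_text = raw
  ), class = "kegg_compound")
}

#' Serialize a parsed record back to KEGG flat-file text
#'
#' Used for cache round-trips and fixture generation; the output parses
#' back to an identical record.
#'
#' @param record a `kegg_reaction` or `kegg_compound`.
#' @return a single string in KEGG flat-file format.
#' @export
serialize_record <- function(record) {
  pad <- function(key, value) {
    if (is.null(value) || !nzchar(value) || is.na(value)) return(character(0))
    sprintf("%-12s%s", key, value)
  }
  if (inherits(record, "kegg_reaction")) {
    lines <- c(
      pad("ENTRY", sprintf("%s                      Reaction", record$id)),
      pad("NAME", record$name),
      pad("EQUATION", record$equation_text),
      pad("ENZYME", paste(record$ec_numbers, collapse = " ")),
      pad("COMMENT", record$comment),
      pad("REMARK", record$remark),
      "///"
    )
  } else if (inherits(record, "kegg_compound")) {
    kind <- if (is_glycan_id(record$id)) "Glycan" else "Compound"
    fmt_mass <- function(x) if (is.na(x)) NA_character_ else format(x, scientific = FALSE)
    lines <- c(
      pad("ENTRY", sprintf("%s                      %s", record$id, kind)),
      pad("NAME", record$name),
      pad("FORMULA", record$formula),
      pad("EXACT_MASS", fmt_mass(record$exact_mass)),
      pad("MOL_WEIGHT", fmt_mass(record$mol_weight)),
      pad("MASS", fmt_mass(record$mass)),
      pad("REMARK", record$remark),
      "///"
    )
  } else {
    stop("serialize_record: unsupported record class")
  }
  paste(lines, collapse = "\n")
}

# participant IDs of a reaction record (substrates then products)
reaction_participants <- function(record) {
  c(record$substrates$id, record$products$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kegg_reaction <- function(x, ...) {
  cat(sprintf("<kegg_reaction> %s%s\n  %s\n", x$id,
              if (nzchar(x$name)) paste0(" (", x$name, ")") else "",
              x$equation_text))
  if (length(x$ec_numbers)) cat("  EC:", paste(x$ec_numbers, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.kegg_compound <- function(x, ...) {
  cat(sprintf("<kegg_compound> %s%s\n", x$id,
              if (nzchar(x$name)) paste0(" (", x$name, ")") else ""))
  if (nzchar(x$formula)) cat("  formula:", x$formula, "\n")
  masses <- c(exact_mass = x$exact_mass, mol_weight = x$mol_weight, mass = x$mass)
  masses <- masses[!is.na(masses)]
  if (length(masses))
    cat(" ", paste(names(masses), masses, sep = "=", collapse = " "), "\n")
  if (!is.na(x$same_as)) cat("  same as:", x$same_as, "\n")
  invisible(x)
}
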