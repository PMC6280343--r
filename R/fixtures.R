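#' Specification for a synthetic mini-KEGG fixture
#'
#' The generator emits a complete local KEGG source (link tables plus
#' reaction/compound/glycan flat-file records) whose composition is
#' known by construction, so every filter branch and matrix path of the
#' pipeline can be exercised and asserted exactly offline.  Category
#' fractions give the share of reactions built to trigger each exclusion
#' rule; the remainder are clean.  Synthetic IDs live in high-numbered
#' namespaces (`R9xxxx`, `C9xxxx`, `G9xxxx`) so they cannot collide with
#' real KEGG IDs in a mixed cache.
#'
#' @param seed integer seed; the same seed yields a byte-identical
#'   fixture directory.
#' @param n_organisms,n_reactions,n_compounds sizes of the synthetic
#'   universe (`n_compounds` is the clean compound pool; special-purpose
#'   compounds are added on top).
#' @param fractions named numeric vector over the categories
#'   `generic_comment`, `polymer`, `possible_polymer`, `pure_glycan`,
#'   `glycan_with_alternative`, `glycan_no_alternative`, `ill_defined`,
#'   `massless`; must sum to at most 1.
#' @param genes_min,genes_max range of genes per owned reaction per
#'   organism.
#' @param overlap probability that an organism owns any given reaction.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_organisms = 3L, n_reactions = 40L,
                         n_compounds = 30L,
                         fractions = c(generic_comment = 0.10, polymer = 0.05,
                                       possible_polymer = 0.05,
                                       pure_glycan = 0.05,
                                       glycan_with_alternative = 0.05,
                                       glycan_no_alternative = 0.05,
                                       ill_defined = 0.05, massless = 0.10),
                         genes_min = 1L, genes_max = 4L, overlap = 0.6) {
  cats <- c("generic_comment", "polymer", "possible_polymer", "pure_glycan",
            "glycan_with_alternative", "glycan_no_alternative", "ill_defined",
            "massless")
  full <- stats::setNames(rep(0, length(cats)), cats)
  full[names(fractions)] <- fractions
  if (sum(full) > 1)
    stop("fixture_spec: category fractions sum to more than 1")
  if (any(full < 0)) stop("fixture_spec: negative category fraction")
  stopifnot(n_organisms >= 1L, n_reactions >= 1L, n_compounds >= 8L,
            genes_min >= 1L, genes_max >= genes_min,
            overlap > 0, overlap <= 1)
  structure(list(seed = as.integer(seed), n_organisms = as.integer(n_organisms),
                 n_reactions = as.integer(n_reactions),
                 n_compounds = as.integer(n_compounds),
                 fractions = full, genes_min = as.integer(genes_min),
                 genes_max = as.integer(genes_max), overlap = overlap),
            class = "fixture_spec")
}

with_fixture_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic mini-KEGG local source
#'
#' Writes the local-source layout ([kegg_source()] `mode = "local"`):
#' `links/<org>_ec.tsv`, `links/ec_rxn.tsv` and `records/<ID>.txt`, plus
#' `manifest.json` holding the ground truth: the expected filter verdict
#' for every reaction, the per-organism reaction and gene sets, and the
#' generic compound list.  The manifest is the oracle the pipeline's
#' outputs are asserted against.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly, with `out_dir` attached.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir = tempfile("minikegg")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(file.path(out_dir, "links"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "records"), recursive = TRUE, showWarnings = FALSE)
  manifest <- with_fixture_rng(spec$seed, build_fixture(spec, out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}

build_fixture <- function(spec, out_dir) {
  n <- spec$n_reactions
  counts <- vapply(spec$fractions, function(f) as.integer(round(f * n)), 0L)
  # a glycan-with-alternative instance needs a second reaction slot for the
  # compound-ID alternative, which is clean by construction
  n_special <- sum(counts) + counts[["glycan_with_alternative"]]
  if (n_special > n)
    stop("fixture_spec: fractions leave no room for alternatives at this n_reactions")

  organisms <- vapply(seq_len(spec$n_organisms), function(i)
    paste0("t", letters[(i - 1) %/% 26 + 1], letters[(i - 1) %% 26 + 1]), "")

  compounds <- list()
  clean_ids <- sprintf("C9%04d", seq_len(spec$n_compounds))
  for (i in seq_along(clean_ids)) {
    compounds[[clean_ids[i]]] <- list(
      id = clean_ids[i], name = sprintf("synthetic compound %d", i),
      formula = sprintf("C%dH%dO%d", i + 1L, 2L * i, i %% 5L + 1L),
      exact_mass = round(stats::runif(1, 50, 500), 4),
      mol_weight = NA_real_, mass = NA_real_, same_as = NA_character_)
  }
  next_c <- spec$n_compounds
  next_g <- 0L
  new_compound <- function(generic = FALSE, mass_only = FALSE) {
    next_c <<- next_c + 1L
    id <- sprintf("C9%04d", next_c)
    compounds[[id]] <<- list(
      id = id, name = sprintf("synthetic compound %d", next_c),
      formula = if (generic) sprintf("C%dH%dOR", next_c, next_c) else
        sprintf("C%dH%dO2", next_c + 1L, 2L * next_c),
      exact_mass = if (generic) {
        if (stats::runif(1) < 0.5) 0 else NA_real_  # 0 and absent both mean generic
      } else round(stats::runif(1, 50, 500), 4),
      mol_weight = NA_real_, mass = NA_real_, same_as = NA_character_)
    id
  }
  new_glycan <- function(same_as = NA_character_, with_mass = TRUE) {
    next_g <<- next_g + 1L
    id <- sprintf("G9%04d", next_g)
    compounds[[id]] <<- list(
      id = id, name = sprintf("synthetic glycan %d", next_g),
      formula = "", exact_mass = NA_real_, mol_weight = NA_real_,
      mass = if (with_mass) round(stats::runif(1, 300, 2000), 2) else NA_real_,
      same_as = same_as)
    id
  }

  draw_clean_equation <- function() {
    k_s <- sample(1:2, 1)
    k_p <- sample(1:2, 1)
    ids <- sample(clean_ids, k_s + k_p)
    coefs <- sample(1:2, k_s + k_p, replace = TRUE)
    term <- function(coef, id) if (coef == 1) id else paste(coef, id)
    paste(paste(mapply(term, coefs[seq_len(k_s)], ids[seq_len(k_s)]),
                collapse = " + "),
          "<=>",
          paste(mapply(term, coefs[k_s + seq_len(k_p)], ids[k_s + seq_len(k_p)]),
                collapse = " + "))
  }

  categories <- c(
    rep("generic_comment", counts[["generic_comment"]]),
    rep("polymer", counts[["polymer"]]),
    rep("possible_polymer", counts[["possible_polymer"]]),
    rep("pure_glycan", counts[["pure_glycan"]]),
    rep("glycan_with_alternative", counts[["glycan_with_alternative"]]),
    rep("glycan_no_alternative", counts[["glycan_no_alternative"]]),
    rep("ill_defined", counts[["ill_defined"]]),
    rep("massless", counts[["massless"]]))
  categories <- c(categories, rep("clean", n - n_special))

  reactions <- list()
  labels <- list()
  rid_counter <- 0L
  new_rid <- function() {
    rid_counter <<- rid_counter + 1L
    sprintf("R9%04d", rid_counter)
  }

  for (cat_ in categories) {
    rid <- new_rid()
    rec <- list(id = rid, name = sprintf("synthetic reaction %s", rid),
                comment = "", remark = "")
    label <- list(category = cat_, expected_status = "kept",
                  expected_category = "none")
    if (cat_ == "clean") {
      rec$equation <- draw_clean_equation()
    } else if (cat_ == "generic_comment") {
      rec$equation <- draw_clean_equation()
      rec$remark <- sample(c("Generic reaction", "General reaction",
                             "General carbohydrate reaction"), 1)
      label$expected_status <- "omitted"
      label$expected_category <- "generic_comment"
    } else if (cat_ == "polymer") {
      ids <- sample(clean_ids, 3)
      rec$equation <- sprintf("(n+1) %s + %s <=> n %s + %s",
                              ids[1], ids[2], ids[1], ids[3])
      label$expected_status <- "omitted"
      label$expected_category <- "polymer"
    } else if (cat_ == "possible_polymer") {
      rec$equation <- draw_clean_equation()
      rec$comment <- "may act in polymerization of the substrate"
      label$expected_status <- "omitted"
      label$expected_category <- "possible_polymer"
    } else if (cat_ == "pure_glycan") {
      g1 <- new_glycan(with_mass = TRUE)
      g2 <- new_glycan(with_mass = TRUE)
      rec$equation <- sprintf("%s <=> %s", g1, g2)
      label$expected_status <- "omitted"
      label$expected_category <- "glycan_only_omitted"
    } else if (cat_ == "glycan_with_alternative") {
      c_sub <- new_compound()
      c_prod <- new_compound()
      ctx <- sample(clean_ids, 2)
      g_sub <- new_glycan(same_as = c_sub)
      g_prod <- new_glycan(same_as = c_prod)
      rec$equation <- sprintf("%s + %s <=> %s + %s", g_sub, ctx[1], g_prod, ctx[2])
      alt_rid <- new_rid()
      reactions[[alt_rid]] <- list(
        id = alt_rid, name = sprintf("synthetic reaction %s", alt_rid),
        equation = sprintf("%s + %s <=> %s + %s", c_sub, ctx[1], c_prod, ctx[2]),
        comment = "", remark = "")
      labels[[alt_rid]] <- list(category = "clean", expected_status = "kept",
                                expected_category = "none")
      label$expected_status <- "kept"
      label$expected_category <- "glycan_replaced"
      label$replacement <- alt_rid
    } else if (cat_ == "glycan_no_alternative") {
      g <- new_glycan(with_mass = TRUE)
      ids <- sample(clean_ids, 2)
      rec$equation <- sprintf("%s + %s <=> %s", g, ids[1], ids[2])
      label$expected_status <- "kept_with_attention"
      label$expected_category <- "glycan_kept_no_alternative"
    } else if (cat_ == "ill_defined") {
      ids <- sample(clean_ids, 3)
      rec$equation <- sprintf("%s + %s <=> %s + %s", ids[1], ids[2], ids[2], ids[3])
      label$expected_status <- "omitted"
      label$expected_category <- "ill_defined"
    } else if (cat_ == "massless") {
      generic_id <- new_compound(generic = TRUE)
      ids <- sample(clean_ids, 2)
      rec$equation <- sprintf("%s + %s <=> %s", generic_id, ids[1], ids[2])
      label$expected_status <- "omitted"
      label$expected_category <- "massless_compound"
    }
    reactions[[rid]] <- rec
    labels[[rid]] <- label
  }

  # gene/EC linkage: one EC per reaction, random organism ownership
  rids <- sort(names(reactions))
  ecs <- stats::setNames(sprintf("8.%d.1.1", seq_along(rids)), rids)
  org_links <- stats::setNames(vector("list", length(organisms)), organisms)
  org_reactions <- stats::setNames(vector("list", length(organisms)), organisms)
  org_genes <- stats::setNames(vector("list", length(organisms)), organisms)
  for (org in organisms) {
    org_links[[org]] <- data.frame(source = character(0), target = character(0))
    org_genes[[org]] <- list()
  }
  for (rid in rids) {
    owners <- organisms[stats::runif(length(organisms)) < spec$overlap]
    if (length(owners) == 0L) owners <- sample(organisms, 1)
    for (org in owners) {
      k <- sample(spec$genes_min:spec$genes_max, 1)
      genes <- sprintf("%s:g%s_%d", org, sub("^R", "", rid), seq_len(k))
      org_links[[org]] <- rbind(org_links[[org]],
                                data.frame(source = genes, target = ecs[[rid]]))
      org_reactions[[org]] <- c(org_reactions[[org]], rid)
      org_genes[[org]][[rid]] <- genes
    }
  }

  # write the local-source layout
  for (org in organisms) {
    tab <- unique(org_links[[org]])
    tab <- tab[order(tab$source, tab$target), , drop = FALSE]
    write_link_tsv(tab, file.path(out_dir, "links", paste0(org, "_ec.tsv")))
  }
  ec_tab <- data.frame(source = unname(ecs), target = rids)
  ec_tab <- ec_tab[order(ec_tab$source, ec_tab$target), , drop = FALSE]
  write_link_tsv(ec_tab, file.path(out_dir, "links", "ec_rxn.tsv"))

  for (rid in rids) {
    rec <- reactions[[rid]]
    obj <- structure(list(id = rec$id, name = rec$name,
                          equation_text = rec$equation,
                          ec_numbers = ecs[[rid]],
                          comment = rec$comment, remark = rec$remark),
                     class = "kegg_reaction")
    writeLines(serialize_record(obj),
               file.path(out_dir, "records", paste0(rid, ".txt")))
  }
  generic_compounds <- character(0)
  for (cid in sort(names(compounds))) {
    cmp <- compounds[[cid]]
    remark <- if (!is.na(cmp$same_as)) sprintf("Same as: %s", cmp$same_as) else ""
    obj <- structure(list(id = cmp$id, name = cmp$name, formula = cmp$formula,
                          exact_mass = cmp$exact_mass,
                          mol_weight = cmp$mol_weight, mass = cmp$mass,
                          remark = remark, same_as = cmp$same_as),
                     class = "kegg_compound")
    if (is_generic_compound(obj)) generic_compounds <- c(generic_compounds, cid)
    writeLines(serialize_record(obj),
               file.path(out_dir, "records", paste0(cid, ".txt")))
  }

  list(seed = spec$seed,
       organisms = organisms,
       n_reactions = length(rids),
       reactions = labels[rids],
       org_reactions = lapply(org_reactions, function(x) sort(unique(x))),
       org_genes = org_genes,
       generic_compounds = generic_compounds,
       compound_ids = sort(names(compounds)))
}

#' The five-strain worked-example fixture
#'
#' Encodes the per-strain gene lists of the five K-12 strains as annotated in KEGG for the first reactions
#' of the KEGG reaction list across the five *E. coli* K-12 strains
#' (`eco`, `ecj`, `ecd`, `ebw`, `ecok`) as a local source, so the ORG
#' report reproduces the known Sum/Total/Genes summaries (e.g. R00014:
#' present in all five strains with per-strain gene counts 6,6,4,6,6,
#' summarized as `"4;6"`).  Reactions with no genes in any strain
#' (R00001, R00002, ...) are present in the reaction list as empty rows.
#'
#' @param out_dir output directory (created if needed).
#' @return the local-source directory path.
#' @export
k12_fixture <- function(out_dir = tempfile("k12fix")) {
  dir.create(file.path(out_dir, "links"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "records"), recursive = TRUE, showWarnings = FALSE)
  genes <- k12_strain_genes()
  orgs <- c("eco", "ecj", "ecd", "ebw", "ecok")
  all_rxns <- c("R00001", "R00002", "R00004", "R00005", "R00006", "R00008",
                "R00009", "R00010", "R00011", "R00012", "R00013", "R00014",
                "R00015", "R00017")
  ecs <- stats::setNames(sprintf("9.9.9.%d", seq_along(all_rxns)), all_rxns)
  for (org in orgs) {
    rows <- list()
    for (rxn in names(genes)) {
      g <- genes[[rxn]][[org]]
      if (length(g))
        rows[[rxn]] <- data.frame(source = paste0(org, ":", g), target = ecs[[rxn]])
    }
    tab <- do.call(rbind, rows)
    tab <- unique(tab[order(tab$source, tab$target), , drop = FALSE])
    write_link_tsv(tab, file.path(out_dir, "links", paste0(org, "_ec.tsv")))
  }
  ec_tab <- data.frame(source = unname(ecs), target = all_rxns)
  ec_tab <- ec_tab[order(ec_tab$source, ec_tab$target), , drop = FALSE]
  write_link_tsv(ec_tab, file.path(out_dir, "links", "ec_rxn.tsv"))
  out_dir
}

# per-strain gene lists of the five K-12 strains as annotated in KEGG for the worked example
k12_strain_genes <- function() {
  list(
    R00004 = list(eco = "b4226", ecj = "JW4185", ecd = "ECDH10B_4421",
                  ebw = "BWG_3936", ecok = "ECMDS42_3668"),
    R00006 = list(
      eco = c("b0078", "b3670", "b0077", "b3671", "b3769"),
      ecj = c("JW0077", "JW3645", "JW0076", "JW3646", "JW3742"),
      ecd = c("ECDH10B_3853", "ECDH10B_3958", "ECDH10B_3854"),
      ebw = c("BWG_0073", "BWG_0074", "BWG_3454", "BWG_3361", "BWG_3362"),
      ecok = c("ECMDS42_3207", "ECMDS42_0071", "ECMDS42_0072", "ECMDS42_3105",
               "ECMDS42_3106")),
    R00009 = list(
      eco = c("b1732", "b3942"), ecj = c("JW1721", "JW3914"),
      ecd = c("ECDH10B_1870", "ECDH10B_4131"),
      ebw = c("BWG_1545", "BWG_3611"),
      ecok = c("ECMDS42_1407", "ECMDS42_3380")),
    R00010 = list(
      eco = c("b1197", "b3519"), ecj = c("JW3487", "JW1186"),
      ecd = c("ECDH10B_3696", "ECDH10B_1250"),
      ebw = c("BWG_3208", "BWG_1022"),
      ecok = c("ECMDS42_2954", "ECMDS42_0984")),
    R00013 = list(eco = "b0507", ecj = "JW0495", ecd = "ECDH10B_0463",
                  ebw = "BWG_0384", ecok = "ECMDS42_0400"),
    R00014 = list(
      eco = c("b0114", "b0078", "b3670", "b0077", "b3671", "b3769"),
      ecj = c("JW0110", "JW0077", "JW3645", "JW0076", "JW3646", "JW3742"),
      ecd = c("ECDH10B_0094", "ECDH10B_3853", "ECDH10B_3958", "ECDH10B_3854"),
      ebw = c("BWG_0073", "BWG_0074", "BWG_3454", "BWG_3361", "BWG_3362",
              "BWG_0107"),
      ecok = c("ECMDS42_3207", "ECMDS42_0071", "ECMDS42_0072", "ECMDS42_0105",
               "ECMDS42_3105", "ECMDS42_3106")),
    R00017 = list(eco = "b3518", ecj = "JW3486", ecd = "ECDH10B_3695",
                  ebw = "BWG_3207", ecok = "ECMDS42_2953"))
}

#' Fixture records for two canonical glycan-translation cases
#'
#' Builds, in code, the reaction and compound records of the two
#' documented glycan cases: the hydrolysis written with glycan IDs
#' (`G00124 + C00001 <=> G00123 + C00124`) whose participants
#' cross-reference the compounds C06136/C06135, its compound-ID
#' alternative (`C06136 + C00001 <=> C06135 + C00124`), and the
#' reaction `G01977 + C00001 <=> G13073 + C00124` whose glycans have no
#' compound cross-reference.  C06136 is a generic compound (residue
#' formula, no mass), so the alternative reaction is itself flagged and
#' omitted at the compound screen -- the intended behavior of the replacement-plus-screening chain.
#'
#' @return list with `reactions` and `compounds`, each a named list of
#'   parsed records.
#' @export
glycan_example_records <- function() {
  rxn <- function(id, equation, name = "") {
    parse_reaction_record(serialize_record(structure(
      list(id = id, name = name, equation_text = equation,
           ec_numbers = character(0), comment = "", remark = ""),
      class = "kegg_reaction")))
  }
  cmp <- function(id, formula = "", exact_mass = NA_real_, mol_weight = NA_real_,
                  mass = NA_real_, same_as = NA_character_, name = "") {
    remark <- if (!is.na(same_as)) sprintf("Same as: %s", same_as) else ""
    parse_compound_record(serialize_record(structure(
      list(id = id, name = name, formula = formula, exact_mass = exact_mass,
           mol_weight = mol_weight, mass = mass, remark = remark,
           same_as = same_as), class = "kegg_compound")))
  }
  list(
    reactions = list(
      R05994 = rxn("R05994", "G00124 + C00001 <=> G00123 + C00124"),
      R05112 = rxn("R05112", "C06136 + C00001 <=> C06135 + C00124"),
      R07807 = rxn("R07807", "G01977 + C00001 <=> G13073 + C00124")),
    compounds = list(
      C00001 = cmp("C00001", formula = "H2O", exact_mass = 18.0106,
                   mol_weight = 18.0153, name = "H2O"),
      C00124 = cmp("C00124", formula = "C6H12O6", exact_mass = 180.0634,
                   mol_weight = 180.1559, name = "D-Galactose"),
      C06135 = cmp("C06135", formula = "C39H69N2O19R", name = "synthetic stand-in"),
      C06136 = cmp("C06136", formula = "C45H79N2O23R", name = "synthetic stand-in"),
      G00124 = cmp("G00124", mass = 1210.43, same_as = "C06136"),
      G00123 = cmp("G00123", mass = 1048.38, same_as = "C06135"),
      G01977 = cmp("G01977", mass = 1385.26),
      G13073 = cmp("G13073", mass = 1223.21)))
}
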