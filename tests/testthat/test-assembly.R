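# run the linkage+filtering stages of a generated fixture in-code
fixture_pipeline <- function(man) {
  src <- kegg_source("local", root = attr(man, "out_dir"), cache_dir = tempfile())
  ge <- lapply(stats::setNames(nm = man$organisms),
               function(o) fetch_gene_ec_links(src, o))
  matrices <- build_or_matrix(ge, fetch_ec_reaction_links(src))
  recs <- fetch_records(src, reaction_universe(matrices))$records
  cmps <- fetch_records(src, man$compound_ids)$records
  report <- apply_filters(recs, cmps)
  list(src = src, matrices = matrices, records = recs, compounds = cmps,
       report = report)
}

test_that("consolidated model unions reactions with OR-joined GPRs", {
  man <- generate_fixture(fixture_spec(seed = 31, n_reactions = 25), tempfile())
  p <- fixture_pipeline(man)
  model <- build_consolidated(p$report, p$records, p$matrices, p$compounds)

  kept_ids <- names(Filter(function(v)
    v$status %in% c("kept", "kept_with_attention") &&
      v$category != "glycan_replaced", p$report$verdicts))
  expect_setequal(setdiff(model$reactions$model_id, kept_ids), character(0))

  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    genes <- strsplit(r$gpr, " or ", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    # GPR soundness: every token appears in the ORG matrix for some organism
    src_rxns <- r$annotations[[1]]$gene_sources
    org_pool <- sort(unique(unlist(lapply(man$organisms, function(o)
      unlist(man$org_genes[[o]][src_rxns])))))
    expect_setequal(genes, org_pool)
    expect_false(is.unsorted(genes))
    # bounds symmetric, reversible
    expect_equal(r$lower_bound, -r$upper_bound)
    expect_true(r$reversible)
    # S column matches the stoichiometry exactly
    st <- r$stoichiometry[[1]]
    col <- model$S[, r$model_id]
    expect_equal(col[names(st)], st)
    expect_equal(sum(col != 0), length(st))
    expect_true(any(st < 0) && any(st > 0))
  }
  # all metabolites in the default cytosol compartment, annotated
  expect_true(all(model$metabolites$compartment == "c"))
  expect_equal(model$compartments, c(c = "cytosol"))
  expect_true(all(nzchar(model$metabolites$kegg_id)))
})

test_that("worked-example gene lists produce the 28-gene OR rule", {
  dirp <- k12_fixture()
  src <- kegg_source("local", root = dirp, cache_dir = tempfile())
  orgs <- c("eco", "ecj", "ecd", "ebw", "ecok")
  ge <- lapply(stats::setNames(nm = orgs), function(o) fetch_gene_ec_links(src, o))
  matrices <- build_or_matrix(ge, fetch_ec_reaction_links(src))
  # simple clean records for the gene-bearing reactions
  universe <- reaction_universe(matrices)
  recs <- stats::setNames(lapply(seq_along(universe), function(i)
    make_reaction(universe[i], sprintf("C9%04d <=> C9%04d", i, i + 100L))),
    universe)
  cmps <- clean_compounds_for(recs)
  report <- apply_filters(recs, cmps)
  model <- build_consolidated(report, recs, matrices, cmps)
  gpr <- model$reactions$gpr[model$reactions$model_id == "R00014"]
  genes <- strsplit(gpr, " or ", fixed = TRUE)[[1]]
  expect_length(genes, 28)  # 6+6+4+6+6 genes across the five strains
  expect_true("eco:b0114" %in% genes && "ecd:ECDH10B_0094" %in% genes)
})

test_that("single models restrict the consolidated model per organism", {
  man <- generate_fixture(fixture_spec(seed = 37, n_organisms = 3,
                                       n_reactions = 25), tempfile())
  p <- fixture_pipeline(man)
  consolidated <- build_consolidated(p$report, p$records, p$matrices, p$compounds)
  singles <- lapply(stats::setNames(nm = man$organisms),
                    function(o) build_single(consolidated, p$matrices, o))

  # union identity: consolidated reactions = union of single models'
  expect_setequal(consolidated$reactions$model_id,
                  unique(unlist(lapply(singles, function(m) m$reactions$model_id))))

  for (org in man$organisms) {
    m <- singles[[org]]
    # restriction oracle over the OR matrix, through glycan replacements
    expected <- vapply(consolidated$reactions$model_id, function(rid) {
      srcs <- consolidated$reactions$annotations[[
        which(consolidated$reactions$model_id == rid)]]$gene_sources
      any(p$matrices$or_matrix[org, srcs] == 1L)
    }, TRUE)
    expect_setequal(m$reactions$model_id,
                    consolidated$reactions$model_id[expected])
    # GPRs restricted to the organism's genes
    genes <- unlist(strsplit(m$reactions$gpr, " or ", fixed = TRUE))
    genes <- genes[nzchar(genes)]
    expect_true(all(startsWith(genes, paste0(org, ":"))))
    # no orphaned metabolites
    used <- sort(unique(unlist(lapply(m$reactions$stoichiometry, names))))
    expect_setequal(m$metabolites$model_id, used)
  }
  expect_error(build_single(consolidated, p$matrices, "zzz"), "not in the query")
})

test_that("community models are disjoint compartment unions with invertible suffixes", {
  man <- generate_fixture(fixture_spec(seed = 41, n_organisms = 3,
                                       n_reactions = 20), tempfile())
  p <- fixture_pipeline(man)
  consolidated <- build_consolidated(p$report, p$records, p$matrices, p$compounds)
  singles <- lapply(stats::setNames(nm = man$organisms),
                    function(o) build_single(consolidated, p$matrices, o))
  community <- build_community(unname(singles))

  expect_equal(nrow(community$reactions),
               sum(vapply(singles, function(m) nrow(m$reactions), 0L)))
  expect_equal(length(community$compartments), length(singles))

  # no sharing between compartments: every reaction's metabolites stay home
  for (j in seq_len(nrow(community$reactions))) {
    st <- community$reactions$stoichiometry[[j]]
    org <- sub("^.*_", "", community$reactions$model_id[j])
    expect_true(all(endsWith(names(st), paste0("_", org))))
  }
  comp <- connected_components(community)
  expect_gte(nrow(comp$sizes), length(singles))

  # suffix invertibility
  back <- split_community(community)
  for (org in man$organisms) {
    a <- singles[[org]]; b <- back[[org]]
    expect_equal(a$reactions$model_id, b$reactions$model_id)
    expect_equal(a$metabolites$model_id, b$metabolites$model_id)
    expect_equal(as.matrix(a$S), as.matrix(b$S))
  }
  expect_error(build_community(list(singles[[1]], singles[[1]])), "duplicate")
})

test_that("replaced glycan reactions enter through their compound alternative", {
  ex <- glycan_example_records()
  # rebuild with a non-generic C06136 stand-in so the alternative survives
  cmp <- ex$compounds
  cmp$C06136 <- make_compound("C06136", formula = "C45H79N2O23", exact_mass = 1000)
  cmp$C06135 <- make_compound("C06135", formula = "C39H69N2O19", exact_mass = 900)
  recs <- ex$reactions["R05994"]
  universe <- ex$reactions
  report <- apply_filters(recs, cmp, universe = universe)
  expect_equal(report$verdicts$R05994$category, "glycan_replaced")

  ge <- list(eco = keggrec:::new_link_table("eco:b0001", "1.1.1.1", "gene-ec"))
  er <- keggrec:::new_link_table("1.1.1.1", "R05994", "ec-reaction")
  matrices <- build_or_matrix(ge, er)
  model <- build_consolidated(report, recs, matrices, cmp, universe = universe)
  expect_equal(model$reactions$model_id, "R05112")
  expect_equal(model$reactions$gpr, "eco:b0001")  # genes carried over
  expect_setequal(model$metabolites$model_id,
                  c("C06136", "C00001", "C06135", "C00124"))
})

test_that("models survive a lossless JSON round-trip", {
  man <- generate_fixture(fixture_spec(seed = 43, n_reactions = 15), tempfile())
  p <- fixture_pipeline(man)
  model <- build_consolidated(p$report, p$records, p$matrices, p$compounds)
  path <- tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(model[setdiff(names(model), "S")],
               back[setdiff(names(back), "S")])
  expect_equal(as.matrix(model$S), as.matrix(back$S))
})

test_that("SBML export is structurally valid and carries annotations", {
  man <- generate_fixture(fixture_spec(seed = 47, n_reactions = 15), tempfile())
  p <- fixture_pipeline(man)
  model <- build_consolidated(p$report, p$records, p$matrices, p$compounds)
  path <- tempfile(fileext = ".xml")
  write_sbml(model, path)
  expect_true(validate_sbml(path))
  doc <- xml2::read_xml(path)
  txt <- as.character(doc)
  expect_match(txt, "identifiers.org/kegg.reaction")
  expect_match(txt, "identifiers.org/kegg.compound")
  # attention-marked reactions carry their note
  flagged <- model$reactions$model_id[nzchar(model$reactions$rxn_attention)]
  if (length(flagged)) expect_match(txt, "rxnAttention")
})
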