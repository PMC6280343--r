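test_that("generic/general remark and comment triggers are case-insensitive", {
  expect_true(is_generic_comment(make_reaction("R90001", "C90001 <=> C90002",
                                               remark = "General reaction")))
  expect_true(is_generic_comment(make_reaction("R90002", "C90001 <=> C90002",
                                               comment = "generic reaction of family X")))
  expect_true(is_generic_comment(make_reaction("R90003", "C90001 <=> C90002",
                                               remark = "A GENERAL case")))
  expect_false(is_generic_comment(make_reaction("R90004", "C90001 <=> C90002")))
})

test_that("polymer detection is structural, not numeric", {
  expect_true(is_polymer(make_reaction("R90001",
                                       "(n+1) C90001 <=> n C90001 + C90009")))
  expect_true(is_polymer(make_reaction("R90002", "m C90001 <=> C90002")))
  expect_false(is_polymer(make_reaction("R90003",
                                        "C06136 + C00001 <=> C06135 + C00124")))
  expect_false(is_polymer(make_reaction("R90004", "2 C90002 <=> 2 C90008")))
  expect_true(is_possible_polymer(make_reaction(
    "R90005", "C90001 <=> C90002", comment = "Involved in polymerization")))
  expect_false(is_possible_polymer(make_reaction("R90006", "C90001 <=> C90002")))
})

test_that("ill-defined means a shared species across the equation sides", {
  expect_true(is_ill_defined(make_reaction(
    "R90001", "C00001 + C00002 <=> C00002 + C00009")))
  expect_true(is_ill_defined(make_reaction("R90002", "C00001 <=> C00001")))
  expect_false(is_ill_defined(make_reaction(
    "R90003", "C06136 + C00001 <=> C06135 + C00124")))
})

test_that("generic compounds are those with no positive mass in any field", {
  expect_true(is_generic_compound(make_compound(
    "C06136", formula = "C45H79N2O23R", exact_mass = NA_real_)))
  expect_true(is_generic_compound(make_compound("C90001", exact_mass = 0)))
  expect_false(is_generic_compound(make_compound("C00001", exact_mass = 18.0106)))
  # glycan with only a mass field, but a specific one: included
  expect_false(is_generic_compound(make_compound(
    "G90001", exact_mass = NA_real_, mass = 1234.5)))
  expect_true(is_generic_compound(make_compound(
    "G90002", exact_mass = NA_real_, mass = NA_real_)))
})

test_that("glycan translation reproduces the documented cases", {
  ex <- glycan_example_records()

  v <- translate_glycan_reaction(ex$reactions$R05994, ex$compounds, ex$reactions)
  expect_equal(v$category, "glycan_replaced")
  expect_equal(v$replacement, "R05112")
  expect_false(v$status == "omitted")

  v <- translate_glycan_reaction(ex$reactions$R07807, ex$compounds, ex$reactions)
  expect_equal(v$status, "kept_with_attention")
  expect_equal(v$category, "glycan_kept_no_alternative")
  expect_true(nzchar(v$attention_text))

  pure <- make_reaction("R90001", "G01977 <=> G13073")
  v <- translate_glycan_reaction(pure, ex$compounds, ex$reactions)
  expect_equal(v$status, "omitted")
  expect_equal(v$category, "glycan_only_omitted")
})

test_that("a full translation landing on a generic compound is omitted", {
  rxn <- make_reaction("R90001", "G90001 <=> G90002")
  compounds <- list(
    G90001 = make_compound("G90001", exact_mass = NA_real_, mass = 900,
                           same_as = "C90001"),
    G90002 = make_compound("G90002", exact_mass = NA_real_, mass = 700,
                           same_as = "C90002"),
    C90001 = make_compound("C90001", exact_mass = NA_real_),  # generic
    C90002 = make_compound("C90002", exact_mass = 300))
  v <- translate_glycan_reaction(rxn, compounds, list(rxn))
  expect_equal(v$category, "glycan_only_omitted")
  expect_match(v$attention_text, "C90001")
})

test_that("filter pipeline partitions a constructed fixture as designed", {
  recs <- list(
    make_reaction("R90001", "C90001 + C90002 <=> C90003", remark = "Generic reaction"),
    make_reaction("R90002", "C90001 <=> C90004", remark = "General reaction"),
    make_reaction("R90003", "(n+1) C90001 <=> n C90001 + C90005"),
    make_reaction("R90004", "C90001 + C90006 <=> C90006 + C90003"),
    make_reaction("R90005", "G90001 <=> G90002"),
    make_reaction("R90006", "C90007 + C90001 <=> C90003"),
    make_reaction("R90007", "C90001 <=> C90002"),
    make_reaction("R90008", "C90002 <=> C90003"),
    make_reaction("R90009", "C90003 <=> C90004"),
    make_reaction("R90010", "C90004 <=> 2 C90008"))
  names(recs) <- vapply(recs, `[[`, "", "id")
  compounds <- clean_compounds_for(recs)
  compounds$C90007 <- make_compound("C90007", exact_mass = NA_real_)  # massless
  compounds$G90001 <- make_compound("G90001", exact_mass = NA_real_, mass = 500)
  compounds$G90002 <- make_compound("G90002", exact_mass = NA_real_, mass = 600)

  report <- apply_filters(recs, compounds)
  expect_equal(report$total_input, 10)
  expect_equal(report$total_omitted, 6)
  expect_equal(report$total_kept, 4)
  expect_equal(unname(report$category_counts[c("generic_comment", "polymer",
                                               "ill_defined",
                                               "glycan_only_omitted",
                                               "massless_compound")]),
               c(2L, 1L, 1L, 1L, 1L))
  expect_equal(report$generic_compounds, "C90007")
  # every omitted or flagged verdict explains itself
  for (v in report$verdicts) {
    if (v$status != "kept" || v$category != "none")
      expect_true(nzchar(v$attention_text))
  }
  # compound screen only evaluates survivors of the reaction-level filters:
  # C90005 occurs only in the omitted polymer reaction
  expect_false("C90005" %in% report$evaluated_compounds)
  expect_true("C90007" %in% report$evaluated_compounds)
})

test_that("verdicts partition the input and are order-independent", {
  man <- generate_fixture(fixture_spec(seed = 23, n_reactions = 30), tempfile())
  src <- kegg_source("local", root = attr(man, "out_dir"), cache_dir = tempfile())
  ids <- sort(names(man$reactions))
  recs <- fetch_records(src, ids)$records
  cmps <- fetch_records(src, man$compound_ids)$records
  r1 <- apply_filters(recs, cmps)
  r2 <- apply_filters(rev(recs), cmps)
  expect_equal(r1$verdicts, r2$verdicts)
  statuses <- vapply(r1$verdicts, `[[`, "", "status")
  expect_equal(sum(statuses == "omitted") + sum(statuses != "omitted"),
               r1$total_input)
  expect_equal(sum(r1$category_counts), r1$total_omitted)

  # massless closure: no kept reaction contains a generic compound
  for (v in r1$verdicts) {
    if (v$status == "omitted" || v$category == "glycan_replaced") next
    parts <- keggrec:::reaction_participants(recs[[v$reaction]])
    generic <- vapply(parts, function(p)
      !is.null(cmps[[p]]) && is_generic_compound(cmps[[p]]), TRUE)
    expect_false(any(generic))
  }
})

test_that("omission accounting identities hold on random fixtures", {
  for (seed in c(101, 202, 303)) {
    man <- generate_fixture(fixture_spec(seed = seed, n_reactions = 25),
                            tempfile())
    src <- kegg_source("local", root = attr(man, "out_dir"),
                       cache_dir = tempfile())
    recs <- fetch_records(src, sort(names(man$reactions)))$records
    cmps <- fetch_records(src, man$compound_ids)$records
    rep <- apply_filters(recs, cmps)
    expect_equal(rep$total_input, rep$total_omitted + rep$total_kept)
    expect_equal(sum(rep$category_counts), rep$total_omitted)
    filt <- sum(rep$category_counts[keggrec:::REACTION_FILTER_CATEGORIES])
    expect_equal(rep$filter_percent,
                 trunc(round(100 * filt / rep$total_input, 6) * 100) / 100)
    expect_true(all(rep$generic_compounds %in% rep$evaluated_compounds))
  }
})

test_that("empty input yields an all-zero report", {
  rep <- apply_filters(list(), list())
  expect_equal(rep$total_input, 0)
  expect_equal(rep$omitted_percent, 0)
  expect_equal(rep$generic_compound_percent, 0)
  expect_equal(unname(rep$category_counts), rep(0L, 6))
})

test_that("unresolvable compounds are treated as massless with a warning", {
  recs <- list(R90001 = make_reaction("R90001", "C90001 <=> C90002"))
  cmps <- list(C90001 = make_compound("C90001"))
  expect_warning(rep <- apply_filters(recs, cmps), "not resolvable")
  expect_equal(rep$verdicts$R90001$category, "massless_compound")
  expect_equal(rep$unresolved_compounds, "C90002")
})
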