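
# tiny in-code link tables for composition tests
lt <- function(src, tgt, kind) keggrec:::new_link_table(src, tgt, kind)

test_that("OR matrix composes gene-EC with EC-reaction links", {
  ge <- list(org = lt(c("org:g1", "org:g2"), c("1.1.1.1", "2.2.2.2"), "gene-ec"))
  er <- lt(c("1.1.1.1", "1.1.1.1", "2.2.2.2"),
           c("R00001", "R00002", "R00002"), "ec-reaction")
  m <- build_or_matrix(ge, er)
  expect_equal(as.vector(m$or_matrix["org", c("R00001", "R00002")]), c(1L, 1L))
  expect_equal(m$org_genes$org$R00001, "org:g1")
  expect_equal(m$org_genes$org$R00002, c("org:g1", "org:g2"))
})

test_that("OR matrix equals the boolean matrix-product oracle on random inputs", {
  set.seed(42)
  for (trial in 1:20) {
    orgs <- sprintf("t%s%s", letters[trial %% 26 + 1], letters[1:sample(2:4, 1)])
    ecs <- sprintf("%d.%d.1.1", 1:4, trial %% 9 + 1)
    rxns <- sprintf("R9%04d", 1:6)
    ge <- lapply(stats::setNames(nm = orgs), function(org) {
      n <- sample(1:6, 1)
      lt(sprintf("%s:g%d", org, sample(1:5, n, replace = TRUE)),
         sample(ecs, n, replace = TRUE), "gene-ec")
    })
    pairs <- expand.grid(ec = ecs, rxn = rxns, stringsAsFactors = FALSE)
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.4, ]
    if (nrow(pairs) == 0L) pairs <- data.frame(ec = ecs[1], rxn = rxns[1])
    er <- lt(pairs$ec, pairs$rxn, "ec-reaction")
    m <- build_or_matrix(ge, er)

    # oracle: boolean product of organism-EC and EC-reaction incidences
    rxn_axis <- sort(unique(er$pairs$target))
    ec_axis <- sort(unique(er$pairs$source))
    OE <- matrix(0L, length(orgs), length(ec_axis),
                 dimnames = list(orgs, ec_axis))
    for (org in orgs) {
      hit <- intersect(ge[[org]]$pairs$target, ec_axis)
      OE[org, hit] <- 1L
    }
    ER <- matrix(0L, length(ec_axis), length(rxn_axis),
                 dimnames = list(ec_axis, rxn_axis))
    ER[cbind(match(er$pairs$source, ec_axis), match(er$pairs$target, rxn_axis))] <- 1L
    oracle <- (OE %*% ER) > 0
    expect_equal(m$or_matrix[orgs, rxn_axis] > 0, oracle)

    # universe = union of per-organism reaction sets
    per_org <- lapply(orgs, function(o) rxn_axis[oracle[o, ]])
    expect_equal(reaction_universe(m), sort(unique(unlist(per_org))))
  }
})

test_that("row summaries reproduce the five-strain worked example", {
  dirp <- k12_fixture()
  src <- kegg_source("local", root = dirp, cache_dir = tempfile())
  orgs <- c("eco", "ecj", "ecd", "ebw", "ecok")
  ge <- lapply(stats::setNames(nm = orgs),
               function(o) fetch_gene_ec_links(src, o))
  m <- build_or_matrix(ge, fetch_ec_reaction_links(src))

  r <- summarize_row(m, "R00014")
  expect_equal(r$sum, 5)
  expect_equal(r$total, 1)
  expect_equal(r$genes_summary, "4;6")
  expect_equal(lengths(r$genes_by_organism),
               c(eco = 6L, ecj = 6L, ecd = 4L, ebw = 6L, ecok = 6L))

  expect_equal(summarize_row(m, "R00006")$genes_summary, "3;5")
  expect_equal(summarize_row(m, "R00013")$sum, 5)
  expect_equal(summarize_row(m, "R00013")$genes_summary, "1")

  r0 <- summarize_row(m, "R00001")
  expect_equal(c(r0$sum, r0$total), c(0, 0))
  expect_equal(r0$genes_summary, "0")

  expect_equal(reaction_universe(m),
               c("R00004", "R00006", "R00009", "R00010", "R00013", "R00014",
                 "R00017"))
  expect_error(summarize_row(m, "R99999"), "unknown reaction")
})

test_that("single-organism summaries and degenerate rows behave", {
  ge <- list(tst = lt(sprintf("tst:g%d", 1:3), rep("1.1.1.1", 3), "gene-ec"))
  er <- lt(c("1.1.1.1", "2.2.2.2"), c("R00001", "R00002"), "ec-reaction")
  m <- build_or_matrix(ge, er)
  r <- summarize_row(m, "R00001")
  expect_equal(c(r$sum, r$total), c(1, 1))
  expect_equal(r$genes_summary, "3")

  # organism with zero links warns and yields an all-zero row
  ge0 <- list(tst = lt(sprintf("tst:g%d", 1:2), rep("1.1.1.1", 2), "gene-ec"),
              emp = lt(character(0), character(0), "gene-ec"))
  expect_warning(m0 <- build_or_matrix(ge0, er), "no gene-EC links")
  expect_equal(sum(m0$or_matrix["emp", ]), 0L)
})

test_that("summaries are invariant under organism permutation and monotone", {
  man <- generate_fixture(fixture_spec(seed = 5, n_organisms = 4,
                                       n_reactions = 15), tempfile())
  src <- kegg_source("local", root = attr(man, "out_dir"), cache_dir = tempfile())
  orgs <- man$organisms
  ge <- lapply(stats::setNames(nm = orgs), function(o) fetch_gene_ec_links(src, o))
  er <- fetch_ec_reaction_links(src)
  m1 <- build_or_matrix(ge, er)
  m2 <- build_or_matrix(rev(ge), er)
  for (r in reaction_universe(m1)) {
    a <- summarize_row(m1, r); b <- summarize_row(m2, r)
    expect_equal(a$sum, b$sum)
    expect_equal(a$total, b$total)
    expect_equal(a$genes_summary, b$genes_summary)
    # column-sum identity and summary grammar
    expect_equal(a$sum, sum(m1$or_matrix[, r]))
    expect_match(a$genes_summary, "^(0|[0-9]+(;[0-9]+)*)$")
    vals <- as.integer(strsplit(a$genes_summary, ";")[[1]])
    expect_false(is.unsorted(vals, strictly = TRUE))
  }
  # dropping an organism never adds reactions
  m3 <- build_or_matrix(ge[-1], er)
  expect_true(all(reaction_universe(m3) %in% reaction_universe(m1)))
})

test_that("the ORG report renders empty rows as 0/0/0 with empty gene cells", {
  dirp <- k12_fixture()
  src <- kegg_source("local", root = dirp, cache_dir = tempfile())
  orgs <- c("eco", "ecj", "ecd", "ebw", "ecok")
  ge <- lapply(stats::setNames(nm = orgs), function(o) fetch_gene_ec_links(src, o))
  m <- build_or_matrix(ge, fetch_ec_reaction_links(src))
  df <- org_report(m)
  expect_equal(names(df), c("KEGG ID", orgs, "Sum", "Total", "Genes"))
  r1 <- df[df$`KEGG ID` == "R00001", ]
  expect_equal(unname(unlist(r1[, c("Sum", "Total", "Genes")])),
               c("0", "0", "0"))
  expect_equal(unname(unlist(r1[, orgs])), rep("", 5))
  r14 <- df[df$`KEGG ID` == "R00014", ]
  expect_match(r14$eco, "eco:b0114")
  expect_equal(lengths(regmatches(r14$eco, gregexpr("eco:", r14$eco))), 6L)
  expect_equal(r14$Genes, "4;6")

  path <- tempfile(fileext = ".tsv")
  org_report(m, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            colClasses = "character")
  expect_equal(nrow(back), nrow(df))
})
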