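# record constructors and independent oracles used across the suite

make_reaction <- function(id, equation, name = "", comment = "", remark = "",
                          ecs = character(0)) {
  parse_reaction_record(serialize_record(structure(
    list(id = id, name = name, equation_text = equation, ec_numbers = ecs,
         comment = comment, remark = remark), class = "kegg_reaction")))
}

make_compound <- function(id, formula = "C2H6O", exact_mass = 100,
                          mol_weight = NA_real_, mass = NA_real_,
                          same_as = NA_character_, name = "") {
  remark <- if (!is.na(same_as)) sprintf("Same as: %s", same_as) else ""
  parse_compound_record(serialize_record(structure(
    list(id = id, name = name, formula = formula, exact_mass = exact_mass,
         mol_weight = mol_weight, mass = mass, remark = remark,
         same_as = same_as), class = "kegg_compound")))
}

# compound map covering a set of reaction records, all with positive mass
clean_compounds_for <- function(records) {
  ids <- sort(unique(unlist(lapply(records, function(r)
    c(r$substrates$id, r$products$id)))))
  stats::setNames(lapply(seq_along(ids), function(i)
    make_compound(ids[i], exact_mass = 50 + i)), ids)
}

# minimal model from explicit stoichiometries: list(rxn_id = c(met = coef, ...))
toy_model <- function(stoich, kind = "consolidated", model_id = "toy") {
  mets <- sort(unique(unlist(lapply(stoich, names))))
  metabolites <- data.frame(model_id = mets, kegg_id = mets, name = mets,
                            formula = "", compartment = "c",
                            stringsAsFactors = FALSE)
  rxns <- data.frame(model_id = names(stoich), kegg_id = names(stoich),
                     name = "", equation = "", gpr = "", rxn_attention = "",
                     lower_bound = -1000, upper_bound = 1000, reversible = TRUE,
                     stringsAsFactors = FALSE)
  rxns$stoichiometry <- unname(stoich)
  rxns$annotations <- rep(list(list()), length(stoich))
  keggrec:::new_draft_model(model_id, kind, metabolites, rxns,
                            compartments = c(c = "cytosol"),
                            provenance = list(organisms = "toy", source = "test"))
}

# random sparse bipartite stoichiometry for property tests
random_stoich <- function(n_mets, n_rxns, p_edge = 0.3) {
  mets <- sprintf("C9%04d", seq_len(n_mets))
  stoich <- list()
  for (j in seq_len(n_rxns)) {
    sel <- mets[stats::runif(n_mets) < p_edge]
    if (length(sel) == 0L) sel <- sample(mets, 1)
    coef <- sample(c(-2, -1, 1, 2), length(sel), replace = TRUE)
    stoich[[sprintf("R9%04d", j)]] <- stats::setNames(coef, sel)
  }
  stoich
}

# --- graph oracles (adjacency-list BFS, independent of igraph) ---

# adjacency list of the bipartite graph of a model
oracle_adjacency <- function(model) {
  S <- as.matrix(model$S)
  nodes <- c(rownames(S), colnames(S))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    if (S[i, j] != 0) {
      m <- rownames(S)[i]; r <- colnames(S)[j]
      adj[[m]] <- c(adj[[m]], r)
      adj[[r]] <- c(adj[[r]], m)
    }
  }
  adj
}

oracle_bfs <- function(adj, start) {
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# component partition by repeated BFS
oracle_components <- function(model) {
  adj <- oracle_adjacency(model)
  left <- names(adj)
  comps <- list()
  while (length(left)) {
    dist <- oracle_bfs(adj, left[1])
    members <- names(dist)[!is.na(dist)]
    comps[[length(comps) + 1L]] <- sort(members)
    left <- setdiff(left, members)
  }
  comps
}

# mean over finite unordered-pair distances by all-pairs BFS
oracle_mean_shortest_path <- function(model) {
  adj <- oracle_adjacency(model)
  nodes <- names(adj)
  total <- 0; count <- 0
  for (a in seq_along(nodes)) {
    dist <- oracle_bfs(adj, nodes[a])
    for (b in seq_along(nodes)) {
      if (b <= a) next
      d <- dist[nodes[b]]
      if (!is.na(d)) { total <- total + d; count <- count + 1 }
    }
  }
  if (count == 0) NaN else unname(total / count)
}

oracle_mean_degree <- function(model) {
  adj <- oracle_adjacency(model)
  mean(lengths(adj))
}
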