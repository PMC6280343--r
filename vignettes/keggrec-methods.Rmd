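---
title: "Methods: draft metabolic reconstruction from KEGG annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: draft metabolic reconstruction from KEGG annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keggrec)
```

## The procedure and its assumptions

`keggrec` assembles first-draft genome-scale metabolic reconstructions from
KEGG annotation alone. The pipeline is deliberately simple and transparent:

1. For each query organism, gene→EC-number links are fetched; EC→reaction
   links connect those to the KEGG reaction namespace. Their composition is
   the binary Organisms–Reactions (OR) incidence matrix, and its gene-bearing
   extension (ORG) stores the supporting genes per cell. The OR matrix *is*
   the per-organism reactome: a reaction belongs to an organism iff at least
   one of its genes reaches the reaction through some EC number.
2. Full reaction and compound records are downloaded only for the union
   reactome (reactions present in at least one query organism), then filtered
   (next section).
3. Kept reactions are assembled into consolidated, single-organism and
   community drafts with purely OR-joined GPR rules.

Assumptions inherited from the data source, stated rather than patched:

* **Reversibility.** KEGG reaction records carry no directionality, so every
  draft reaction is reversible. Thermodynamics-based direction assignment is
  downstream curation work, out of scope here.
* **One compartment.** KEGG does not assign reactions to compartments; all
  species sit in a default cytosol. Community models get one compartment per
  organism purely by ID suffixing — with no transport reactions the
  compartments are intentionally disconnected.
* **OR-only GPRs.** KEGG does not record how gene products interact
  (complexes vs isozymes), so genes are joined with `or` only; `and`
  relations are a curation task.
* **Mass/charge balance is KEGG's.** Balance status is taken from the
  annotations; the package does not re-balance equations.

EC numbers with trailing dashes (partially classified activities) are linked
like full ECs: dropping them would silently shrink reactomes. Genes are
resolved to ECs directly; KEGG orthology (KO) could serve as an alternative
intermediate route, but the direct gene–enzyme links are what the linkage
stage is defined on, so KO is noted as a possible extension only.

## Filter rules

Reaction-level screens run first-match-wins, in this order:

| order | category | trigger |
|---|---|---|
| 1 | `generic_comment` | remark **or** comment contains "Generic", "General" or "General reaction" (case-insensitive substring) |
| 2 | `polymer` | equation has symbolic coefficients (`n`, `m`, `(n+1)`, ...) |
| 3 | glycan handling | any `G#####` participant (see below) |
| 4 | `ill_defined` | the same species occurs on both sides of the equation |
| 5 | `possible_polymer` | comment declares polymerization without symbolic coefficients |

then the compound-level screen:

| 6 | `massless_compound` | a surviving reaction contains a compound with no positive mass in any of `EXACT_MASS`, `MOL_WEIGHT`, `MASS` |

The order mirrors the narrative of the omission accounting and makes the
category counts well-defined (one verdict per reaction). The trigger strings
are searched in *both* the comment and remark fields; a stricter variant
would require the textual trigger *in conjunction with* the structural
glycan/polymer tests, but that coupling is rejected here because glycan-only
and polymer reactions must be excluded unconditionally for the draft to have
a steady-state reading at all. Both a structural polymer detector and a
comment-based one are provided, as the two exclusions are reported as
distinct categories.

**Glycan handling.** KEGG keeps carbohydrates in a separate `G` namespace;
some glycans are cross-referenced to ordinary compounds by a "Same as"
remark. For a glycan-containing reaction:

* if every glycan participant translates and a reaction with exactly the
  translated participant multiset exists in the reaction universe, the
  original is *replaced* by that alternative (`glycan_replaced`, the original
  contributes its gene links to the replacement);
* if the participants are all glycans and no alternative exists, it is
  omitted (`glycan_only_omitted`), as is a translation that lands on a
  generic compound;
* a mixed reaction with untranslatable glycans and no alternative is kept
  with a `rxnAttention` mark (`glycan_kept_no_alternative`) for curator
  review.

The alternative is searched in the *global* reaction universe passed to the
filter, not the single organism's reactome: the replacement is a statement
about KEGG's reaction catalogue, not about the organism. Equation matching
ignores orientation (all reactions are reversible). A glycan whose record
carries only the glycan-specific `MASS` field, but a positive one, is *not*
generic: a specific mass is given, so the compound is included.

**Massless screen.** Only compounds participating in reactions that survived
the reaction-level screens are evaluated — omitted reactions' compounds never
enter the generic-compound percentage. Compounds that cannot be resolved in
the record set are conservatively treated as massless and listed separately
in the report.

**Percentage rendering.** All report percentages are truncated (not rounded)
to two decimals. Truncation is the package's rendering convention because it
reproduces the reference accounting consistently across all three headline
percentages (e.g. 390/1626 = 23.985…% renders as 23.98); half-up rounding
would not. A guard at the 6th decimal avoids floating-point artifacts before
truncation.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| flux bounds | ±1000 | mmol·gDW⁻¹·h⁻¹ (nominal) | arbitrary large symmetric bounds for reversible draft reactions; no bound information exists in KEGG |
| compartment token | `c` / "cytosol" | — | common SBML practice for the default compartment |
| community suffix | `_<org>` | — | underscore keeps SBML SIds valid while making the compartment recoverable by suffix stripping |
| REST batch size | 10 | IDs per `get` | the service's documented multi-entry limit |
| retry policy | 3 attempts, linear backoff | s | downloads dominate runtime; correctness never depends on parallelism, so fetching is sequential by default |

Gene IDs are stored verbatim as `org:locus`; the colon is sanitized to `_`
only at SBML serialization (SId validity), with the verbatim form retained in
annotations and `fbc:label`.

## Determinism and ordering

Everything downstream of fetching is order-independent by construction:
link-table pairs are deduplicated and sorted, verdicts are sorted by reaction
ID, metabolites/reactions/GPR genes sort lexicographically, and component
ties break by reaction count, then metabolite count, then smallest member.
Every fetched record is written through a plain-text cache (one file per ID),
so a live run followed by a local rerun over the populated cache is
byte-identical. Degenerate inputs are defined, not errors: an organism with
no gene–EC links yields an all-zero OR row with a warning; an organism owning
no kept reaction yields an empty single model with a warning; an empty filter
input yields an all-zero report.

## Network statistics

Statistics are computed on the **bipartite metabolite–reaction graph** (edge
⇔ nonzero S entry), not on a metabolite projection: the OR-matrix framing of
the reconstruction is explicitly bipartite, and the bipartite graph is the
one on which "a metabolite occurring in exactly one reaction" (blocked) and
"in exactly two reactions with the same S-matrix sign" (same-sign,
unbalanceable at steady state) are natural definitions. Mean shortest path
averages geodesics over same-component pairs only — draft networks are
usually disconnected and infinite distances would be meaningless. The giant
component is the component with most reactions; the reported fraction is its
share of all reactions.

## The synthetic fixture generator

`generate_fixture()` writes a deterministic mini-KEGG (link tables plus
flat-file records) whose composition is known by construction: category
fractions of the reaction budget trigger each filter branch, glycan pairs
come with or without "Same as" cross-references and with dedicated compound
alternatives, generic compounds appear only where a massless omission is
intended, and the manifest records the expected verdict for every reaction
plus the per-organism reaction and gene sets. Defaults (3 organisms, 40
reactions, 30-compound clean pool, 60% ownership probability, 1–4 genes per
owned reaction, 10% generic-comment, 10% massless and 5% for each remaining
special category) give a small universe in which every branch occurs several
times while the whole pipeline runs in well under a second.

The generator emulates record *syntax and bookkeeping*, not biology: it makes
no attempt at realistic degree distributions, pathway structure, EC
multiplicity (each synthetic reaction has exactly one EC) or shared enzymes
across reactions. Passing tests therefore demonstrate that the pipeline's
logic — linkage composition, filter partition, accounting identities,
assembly set algebra, serialization round-trips — is correct on inputs of the
right shape; they say nothing about the curation quality of real KEGG
annotation, and headline counts from live KEGG depend on the database
snapshot and are not reproducible offline by design.

Test and acceptance problem sizes were chosen so the full suite stays small:
property loops use 8–50 generated fixtures of 15–40 reactions and random
bipartite graphs of at most ~40 nodes against hand-written BFS/brute-force
oracles; these sizes already exercise every code path several times over.

## Known limitations

* No biomass, ATP-maintenance, transport or exchange reactions, no
  directionality, no gap-filling — by design; the output is a curation
  starting point.
* The `Total` column is defined as `Sum / number of query organisms`; for
  mixed-species queries it is a fraction of the query list, not of any
  taxonomic group.
* A glycan replacement that lies outside the filtered reaction set enters
  the model without having passed the massless screen itself; within the
  normal pipeline the universe covers all downloaded reactions, so every
  replacement carries its own verdict.
* SBML output is validated structurally (namespaces, SIds, reference
  integrity, reversibility, bounds) by `validate_sbml()`; it is written to
  be L3V1+fbc conformant but is not checked against the official XML schema.
* REST mode implements the standard `link`/`get` verbs with batching,
  write-through caching and retries, but all bundled tests run offline
  against local fixtures.
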