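Package: keggrec
Title: First-Draft Genome-Scale Metabolic Reconstructions from KEGG Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds first-draft genome-scale metabolic network reconstructions
    for any list of KEGG organism identifiers, using only KEGG annotation data
    (gene-EC links, EC-reaction links, reaction and compound records).
    Produces single-organism drafts, a consolidated union draft, and
    multi-compartment community drafts, with OR-joined gene-protein-reaction
    rules and full annotation carry-over.  Applies transparent reaction and
    compound exclusion rules (generic and polymer reactions, glycan-only
    equations with compound-ID translation where cross-references exist,
    ill-defined equations, massless compounds), keeps an auditable omission
    report, computes stoichiometric network statistics (giant component,
    mean degree, mean shortest path, blocked and same-sign metabolites), and
    exports SBML Level 3 with the flux-balance-constraints extension as well
    as a lossless native JSON serialization.  A deterministic synthetic
    mini-KEGG fixture generator allows the whole pipeline to run and be
    tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
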