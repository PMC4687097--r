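Package: proximal
Title: Prediction of Xenobiotic Metabolism from Reaction-Center Lookup Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Phase I (cytochrome P450) and Phase II (transferase)
    biotransformation products of xenobiotic chemicals. Reactant-product
    reaction pairs are aligned by maximum common subgraph search, reaction
    centers are detected as atoms whose KEGG atom type changes, and
    (reaction-center, two-level neighborhood) keys are stored in lookup
    tables together with the structural transformation they index. Applying
    matching transformations to a query molecule enumerates candidate
    metabolites, and Phase I products are ranked by a CYP activity times
    abundance score computed from normalized multi-study enzyme data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    limma,
    optparse
Config/testthat/edition: 3
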