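Package: eqsim
Title: Semantic Similarity for Ontology-Based Entity-Quality Phenotype Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing ontology-based entity-quality (EQ)
    phenotype annotations of phylogenetic character states, as used in
    evolutionary phenomics curation. Parses OBO flat-file ontologies,
    represents post-composed class expressions, generates the subsumer set
    of an EQ annotation by combining component superclasses with the
    superclasses of its combined class expression, and computes four
    ontology-aware similarity metrics: Jaccard similarity over subsumer
    sets, normalized information content of the least common subsumer,
    and partial precision / partial recall with best-match aggregation at
    the character-state level. Includes rank-preference statistics
    (Anderson's A, Friedman's F, paired Wilcoxon signed-rank with exact
    small-sample p-values), a seeded synthetic-data generator emulating
    modes of inter-curator variation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
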