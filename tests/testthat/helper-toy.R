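# Small hand-built fixtures used across the suite.

toy_class <- function(lab, obsolete = FALSE) {
  list(label = lab, synonyms = character(0), obsolete = obsolete)
}

# fin anatomy chain + quality chain, one transitive part_of property
toy_graph <- function() {
  ontology_graph(
    classes = list(
      "U:1" = toy_class("anatomical structure"),
      "U:2" = toy_class("fin"),
      "U:3" = toy_class("pectoral fin"),
      "U:4" = toy_class("pelvic fin"),
      "P:1" = toy_class("quality"),
      "P:2" = toy_class("size"),
      "P:3" = toy_class("increased size"),
      "P:4" = toy_class("decreased size")),
    isa_parents = list("U:2" = "U:1", "U:3" = "U:2", "U:4" = "U:2",
                       "P:2" = "P:1", "P:3" = "P:2", "P:4" = "P:2"),
    properties = list(part_of = list(transitive = TRUE),
                      inheres_in = list(transitive = FALSE),
                      towards = list(transitive = FALSE)))
}

toy_eq <- function(e, q, re = NULL) {
  eq_annotation(expr_named(e), expr_named(q),
                if (!is.null(re)) expr_named(re))
}

# one-state source holding the given annotations
toy_source <- function(id, ...) {
  eqs <- list(...)
  annotation_source(id, list(
    character_state("S", "c1", "s1", "char", "state", annotations = eqs)))
}

obo_lines_minimal <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: A:1", "name: alpha", "",
    "[Term]", "id: A:2", "name: beta", "is_a: A:1", "",
    "[Typedef]", "id: part_of", "is_transitive: true", "")
}
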