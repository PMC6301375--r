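EQ_PROPERTIES <- c("inheres_in", "towards")

# Guarantee the two structural properties of the EQ-to-expression
# transform are declared (non-transitive) on the graph.
ensure_eq_properties <- function(graph) {
  for (p in EQ_PROPERTIES) {
    if (!p %in% names(graph$properties)) {
      graph$properties[[p]] <- list(transitive = FALSE)
    }
  }
  graph
}

#' Transform an EQ annotation into a class expression
#'
#' An EQ annotation corresponds to the class expression
#' `Q and (inheres_in some E)`, extended with `(towards some RE)` when
#' a related entity is present.  This combined expression is the node
#' the annotation denotes in the ad hoc EQ ontology.
#'
#' @param eq A complete `eqsim_eq`.
#' @return An `eqsim_expr`.
#' @export
eq_to_class_expression <- function(eq) {
  stopifnot(inherits(eq, "eqsim_eq"))
  if (!eq$complete) {
    stop("cannot build a class expression for an incomplete EQ; ",
         "incomplete annotations take the zero-score rule instead")
  }
  parts <- list(eq$quality, expr_some("inheres_in", eq$entity))
  if (!is.null(eq$related_entity)) {
    parts <- c(parts, list(expr_some("towards", eq$related_entity)))
  }
  expr_and(parts)
}

triple_key <- function(e, q, re) {
  paste0("T:", e, "\x1f", q, "\x1f", if (is.null(re)) "" else re)
}

#' Subsumers of an EQ annotation
#'
#' Implements the ad hoc subsumer construction: the annotation is split
#' into its E, Q and (optional) RE components, whose individual
#' superclass sets `SE`, `SQ`, `SR` are combined into every E–Q–RE
#' triple `SE x SQ x SR`; separately, the annotation's combined class
#' expression (see [eq_to_class_expression()]) contributes its own
#' structural superclasses.  The two families together are the subsumer
#' universe used by every similarity metric.  They are kept as tagged,
#' disjoint sets: triples with and without an RE never compare equal,
#' and a bare quality superclass inside a triple is distinct from the
#' same class appearing as an expression superclass.
#'
#' Results are memoized per annotation rendering on the graph.
#'
#' @param eq A complete `eqsim_eq`.
#' @param graph An `eqsim_graph`.
#' @return An object of class `eqsim_subsumers` with fields `triples`
#'   (data frame `e`, `q`, `re` of component renderings; `re` is `NA`
#'   for an annotation without a related entity), `expr_supers` (list
#'   of `eqsim_expr`), `keys` (tagged canonical keys of the full
#'   universe), and `owner`.
#' @export
subsumers <- function(eq, graph) {
  stopifnot(inherits(eq, "eqsim_eq"), inherits(graph, "eqsim_graph"))
  if (!eq$complete) stop("subsumers are undefined for an incomplete EQ")
  cache <- graph$cache
  if (is.null(cache$subs)) cache$subs <- new.env(parent = emptyenv())
  key <- eq_render(eq)
  memo <- cache$subs[[key]]
  if (!is.null(memo)) return(memo)

  graph <- ensure_eq_properties(graph)
  se <- vapply(superclasses(graph, eq$entity), render_expr, character(1L))
  sq <- vapply(superclasses(graph, eq$quality), render_expr, character(1L))
  has_re <- !is.null(eq$related_entity)
  sr <- if (has_re) {
    vapply(superclasses(graph, eq$related_entity), render_expr, character(1L))
  } else NA_character_

  grid <- expand.grid(e = se, q = sq, re = sr, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  tkeys <- paste0("T:", grid$e, "\x1f", grid$q, "\x1f",
                  ifelse(is.na(grid$re), "", grid$re))

  expr <- eq_to_class_expression(eq)
  esup <- superclasses(graph, expr)
  xkeys <- paste0("X:", vapply(esup, render_expr, character(1L)))

  out <- structure(list(triples = grid, expr_supers = esup,
                        keys = c(tkeys, xkeys), owner = eq),
                   class = "eqsim_subsumers")
  cache$subs[[key]] <- out
  out
}

#' @export
print.eqsim_subsumers <- function(x, ...) {
  cat("<subsumer set> ", nrow(x$triples), " E-Q-RE triples + ",
      length(x$expr_supers), " expression superclasses (",
      length(x$keys), " total) for ", eq_render(x$owner), "\n", sep = "")
  invisible(x)
}

#' Render a subsumer set as sorted text lines
#'
#' One line per subsumer, `TRIPLE<TAB>e<TAB>q<TAB>re` or
#' `EXPR<TAB>rendering`, sorted — stable across runs, intended for
#' diffing and the `dump-subsumers` CLI command.
#'
#' @param x An `eqsim_subsumers`.
#' @return Character vector of lines.
#' @export
format_subsumers <- function(x) {
  tr <- x$triples
  lines <- c(
    paste("TRIPLE", tr$e, tr$q, ifelse(is.na(tr$re), "-", tr$re), sep = "\t"),
    paste("EXPR", vapply(x$expr_supers, render_expr, character(1L)),
          sep = "\t"))
  sort(lines, method = "radix")
}
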