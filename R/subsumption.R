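#' Named-class ancestors under is_a
#'
#' Reflexive–transitive closure of `is_a` from `term`.  Obsolete terms
#' are excluded from subsumption: querying one is an error, and
#' obsolete ancestors are dropped from every closure.  Results are
#' memoized on the graph.
#'
#' @param graph An `eqsim_graph`.
#' @param term Term id.
#' @return Character vector of term ids, `term` included.
#' @export
term_ancestors <- function(graph, term) {
  cl <- graph$classes[[term]]
  if (is.null(cl)) stop("unknown term id: ", term)
  if (isTRUE(cl$obsolete)) {
    stop("term ", term, " (", cl$label %||% "no label",
         ") is obsolete and excluded from subsumption")
  }
  cache <- graph$cache
  if (is.null(cache$anc)) cache$anc <- new.env(parent = emptyenv())
  memo <- cache$anc[[term]]
  if (!is.null(memo)) return(memo)
  # iterative DFS; acyclicity guaranteed at load
  seen <- character(0)
  stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    if (isTRUE(graph$classes[[t]]$obsolete)) next
    seen <- c(seen, t)
    stack <- c(stack, graph$isa_parents[[t]])
  }
  seen <- sort(seen, method = "radix")
  cache$anc[[term]] <- seen
  seen
}

#' Structural superclasses of a class expression
#'
#' Computes the reflexive set of subsumers of `expr` in the EL-style
#' fragment used for post-composed EQ annotations, under four rules:
#' a named class is subsumed by every `is_a` ancestor (reflexive,
#' transitive); `(p some F)` is subsumed by `(p some F')` for every
#' superclass `F'` of the filler; an intersection is subsumed by every
#' superclass of each conjunct and by itself; and for a transitive
#' property `p`, nested restrictions collapse, `(p some (p some F))`
#' being subsumed by `(p some F')` for every superclass `F'` of `F`
#' (applied to fixpoint).  The result always contains `expr` itself.
#'
#' This reproduces, for the expression shapes an EQ pipeline generates,
#' what an EL reasoner derives over the comprehensive ontology extended
#' with the `OP some U` vocabulary (see
#' [augment_with_existentials()]); named-class logical definitions are
#' outside the fragment.
#'
#' @param graph An `eqsim_graph`.
#' @param expr An `eqsim_expr` whose term ids all exist in `graph`.
#' @return A list of `eqsim_expr`, deduplicated, sorted by canonical
#'   rendering.
#' @export
superclasses <- function(graph, expr) {
  stopifnot(inherits(graph, "eqsim_graph"), inherits(expr, "eqsim_expr"))
  cache <- graph$cache
  if (is.null(cache$sup)) cache$sup <- new.env(parent = emptyenv())
  key <- render_expr(expr)
  memo <- cache$sup[[key]]
  if (!is.null(memo)) return(memo)
  out <- switch(expr$kind,
    named = lapply(term_ancestors(graph, expr$term), expr_named),
    some  = superclasses_some(graph, expr),
    and   = {
      acc <- list(expr)
      for (a in expr$args) acc <- c(acc, superclasses(graph, a))
      acc
    })
  keys <- vapply(out, render_expr, character(1L))
  out <- out[!duplicated(keys)]
  out <- out[order(vapply(out, render_expr, character(1L)), method = "radix")]
  cache$sup[[key]] <- out
  out
}

superclasses_some <- function(graph, expr) {
  p <- expr$property
  if (!p %in% names(graph$properties)) {
    stop("unknown object property: ", p)
  }
  fillers <- superclasses(graph, expr$filler)
  acc <- new.env(parent = emptyenv())
  add <- function(e) {
    k <- render_expr(e)
    if (is.null(acc[[k]])) { acc[[k]] <- e; TRUE } else FALSE
  }
  for (f in fillers) add(expr_some(p, f))
  if (isTRUE(graph$properties[[p]]$transitive)) {
    # collapse (p some (p some F)) -> (p some F'), to fixpoint
    repeat {
      changed <- FALSE
      for (k in ls(acc)) {
        e <- acc[[k]]
        f <- e$filler
        if (f$kind == "some" && identical(f$property, p)) {
          for (g in superclasses(graph, f$filler)) {
            if (add(expr_some(p, g))) changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  mget(ls(acc), envir = acc)
}

#' Does one expression structurally subsume another?
#'
#' `TRUE` iff `super` is among [superclasses()] of `sub`.
#'
#' @param graph An `eqsim_graph`.
#' @param super,sub `eqsim_expr` objects.
#' @export
expr_subsumes <- function(graph, super, sub) {
  render_expr(super) %in%
    vapply(superclasses(graph, sub), render_expr, character(1L))
}
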