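#' Class expressions for post-composed phenotype terms
#'
#' An `eqsim_expr` is the abstract syntax tree of an ontology class
#' expression in the EL-style fragment used for post-composed EQ
#' annotations: a named class, an existential restriction
#' (`property some filler`), or an intersection of two or more
#' expressions.  Intersections are flattened and their conjuncts kept in
#' canonical (lexicographic by rendering) order, so structurally equal
#' expressions always render identically and compare equal.
#'
#' @param term Term identifier string of the form `"PREFIX:LOCAL"`.
#' @name class-expression
NULL

#' @rdname class-expression
#' @return An object of class `eqsim_expr`.
#' @export
expr_named <- function(term) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  structure(list(kind = "named", term = term), class = "eqsim_expr")
}

#' @rdname class-expression
#' @param property Object property name (e.g. `"part_of"`).
#' @param filler An `eqsim_expr`, possibly composite.
#' @export
expr_some <- function(property, filler) {
  stopifnot(is.character(property), length(property) == 1L, nzchar(property))
  if (!inherits(filler, "eqsim_expr")) stop("filler must be an eqsim_expr")
  structure(list(kind = "some", property = property, filler = filler),
            class = "eqsim_expr")
}

#' @rdname class-expression
#' @param ... Two or more `eqsim_expr` conjuncts (nested intersections are
#'   flattened; duplicates removed; order canonicalized).
#' @export
expr_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !inherits(args[[1L]], "eqsim_expr")) {
    args <- args[[1L]]
  }
  flat <- list()
  for (a in args) {
    if (!inherits(a, "eqsim_expr")) stop("conjuncts must be eqsim_expr objects")
    if (a$kind == "and") flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  keys <- vapply(flat, render_expr, character(1L))
  keep <- !duplicated(keys)
  flat <- flat[keep]
  keys <- keys[keep]
  if (length(flat) == 1L) return(flat[[1L]])
  if (length(flat) < 2L) stop("an intersection needs at least two conjuncts")
  flat <- flat[order(keys, method = "radix")]
  structure(list(kind = "and", args = flat), class = "eqsim_expr")
}

#' Render a class expression in canonical text form
#'
#' The canonical rendering is round-trippable through
#' [parse_expression()]: `TERM`, `(p some X)`, `(X and Y and ...)`.
#' Canonical renderings are used as set-membership keys throughout the
#' package, so two expressions are treated as the same class iff they
#' render identically.
#'
#' @param x An `eqsim_expr`.
#' @return A single string.
#' @export
render_expr <- function(x) {
  stopifnot(inherits(x, "eqsim_expr"))
  switch(x$kind,
    named = x$term,
    some  = paste0("(", x$property, " some ", render_expr(x$filler), ")"),
    and   = paste0("(",
                   paste(vapply(x$args, render_expr, character(1L)),
                         collapse = " and "),
                   ")"),
    stop("unknown expression kind: ", x$kind))
}

#' @export
format.eqsim_expr <- function(x, ...) render_expr(x)

#' @export
print.eqsim_expr <- function(x, ...) {
  cat("<class expression> ", render_expr(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.eqsim_expr` <- function(e1, e2) {
  inherits(e2, "eqsim_expr") && identical(render_expr(e1), render_expr(e2))
}

#' Collect every term identifier mentioned in an expression
#' @param x An `eqsim_expr`.
#' @return Character vector of term ids (may repeat a term once).
#' @export
expr_terms <- function(x) {
  switch(x$kind,
    named = x$term,
    some  = expr_terms(x$filler),
    and   = unique(unlist(lapply(x$args, expr_terms))))
}

# --- post-composition grammar -------------------------------------------
#
#   expr := atom | "(" expr ("and" expr)+ ")" | "(" PROP "some" expr ")"
#   atom := CURIE | 'quoted label'
#
# Quoted labels resolve through the graph's labels first, then synonyms;
# an ambiguous or unknown label is an error listing near matches.

tokenize_expression <- function(text) {
  toks <- character(0)
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") { toks <- c(toks, ch); i <- i + 1L; next }
    if (ch == "'") {
      j <- i + 1L
      while (j <= n && substr(text, j, j) != "'") j <- j + 1L
      if (j > n) stop("unterminated quoted label in expression: ", text)
      toks <- c(toks, paste0("'", substr(text, i + 1L, j - 1L), "'"))
      i <- j + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()']$", substr(text, j, j), perl = TRUE)) {
      j <- j + 1L
    }
    toks <- c(toks, substr(text, i, j - 1L))
    i <- j
  }
  toks
}

resolve_atom <- function(atom, graph) {
  if (grepl("^'", atom)) {
    label <- substr(atom, 2L, nchar(atom) - 1L)
    resolve_label(graph, label)
  } else {
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*:\\S+$", atom)) {
      stop("not a CURIE or quoted label: '", atom, "'")
    }
    if (!is.null(graph) && !atom %in% names(graph$classes)) {
      stop("unknown term id: ", atom)
    }
    atom
  }
}

#' Parse a post-composition string into a class expression
#'
#' Accepts the textual grammar used in annotation tables: a bare CURIE or
#' quoted ontology label, an intersection `(X and Y and ...)`, or an
#' existential restriction `(prop some X)`; the three forms nest freely,
#' e.g. `"('gland' and (part_of some ('lateral region' and (part_of some
#' 'pelvis'))))"`.  Quoted labels are resolved against the graph's labels
#' (exact match first, then synonyms; ambiguity is an error).
#'
#' @param text Expression string.
#' @param graph An `eqsim_graph` used to resolve labels and check term
#'   ids; pass `NULL` to skip resolution (CURIEs accepted verbatim).
#' @return A canonical `eqsim_expr`.
#' @export
parse_expression <- function(text, graph = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_expression(text)
  if (length(toks) == 0L) stop("empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() {
    if (pos > length(toks)) stop("unexpected end of expression: ", text)
    t <- toks[[pos]]; pos <<- pos + 1L; t
  }
  parse_one <- function() {
    t <- take()
    if (t == ")") stop("unbalanced parentheses in expression: ", text)
    if (t != "(") return(expr_named(resolve_atom(t, graph)))
    first_tok <- peek()
    # lookahead: "(PROP some ..." is an existential restriction
    if (!is.na(first_tok) && first_tok != "(" &&
        pos + 1L <= length(toks) && toks[[pos + 1L]] == "some") {
      prop <- take(); take()  # PROP, "some"
      if (!is.null(graph) && !prop %in% names(graph$properties)) {
        stop("unknown object property: ", prop)
      }
      filler <- parse_one()
      if (take() != ")") stop("unbalanced parentheses in expression: ", text)
      return(expr_some(prop, filler))
    }
    conjuncts <- list(parse_one())
    while (!is.na(peek()) && peek() == "and") {
      take()
      conjuncts <- c(conjuncts, list(parse_one()))
    }
    if (length(conjuncts) < 2L) {
      stop("expected 'and' or 'some' inside parentheses: ", text)
    }
    if (take() != ")") stop("unbalanced parentheses in expression: ", text)
    expr_and(conjuncts)
  }
  out <- parse_one()
  if (pos <= length(toks)) stop("trailing tokens in expression: ", text)
  out
}
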