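#' Ontology graphs
#'
#' An `eqsim_graph` holds the fragment of an OBO ontology needed for
#' structural subsumption: named classes with labels and synonyms,
#' `is_a` edges, typed relationship edges, and object-property
#' declarations with their transitivity flag.  The `is_a` graph must be
#' acyclic; obsolete classes are retained (so identifiers still resolve
#' in error messages) but excluded from subsumption.
#'
#' @param classes Named list keyed by term id; each element a list with
#'   `label`, `synonyms` (character), `obsolete` (flag).
#' @param isa_parents Named list keyed by child term id; each element a
#'   character vector of parent term ids.
#' @param rel_edges Data frame with columns `subject`, `property`,
#'   `object`.
#' @param properties Named list keyed by property name; each element a
#'   list with a `transitive` flag.
#' @return An `eqsim_graph`.
#' @export
ontology_graph <- function(classes, isa_parents = list(),
                           rel_edges = NULL, properties = list()) {
  if (is.null(rel_edges)) {
    rel_edges <- data.frame(subject = character(0), property = character(0),
                            object = character(0), stringsAsFactors = FALSE)
  }
  ids <- names(classes)
  if (anyDuplicated(ids)) stop("duplicate term ids in class table")
  for (child in names(isa_parents)) {
    ps <- isa_parents[[child]]
    if (!child %in% ids) stop("is_a edge from undeclared class: ", child)
    bad <- setdiff(ps, ids)
    if (length(bad)) {
      stop("is_a edge to undeclared class: ", child, " -> ", bad[[1L]])
    }
  }
  if (nrow(rel_edges)) {
    bad <- setdiff(c(rel_edges$subject, rel_edges$object), ids)
    if (length(bad)) stop("relationship edge endpoint undeclared: ", bad[[1L]])
    badp <- setdiff(unique(rel_edges$property), names(properties))
    if (length(badp)) stop("relationship uses undeclared property: ", badp[[1L]])
  }
  g <- structure(list(classes = classes,
                      isa_parents = isa_parents,
                      rel_edges = rel_edges,
                      properties = properties,
                      cache = new.env(parent = emptyenv())),
                 class = "eqsim_graph")
  cyc <- find_isa_cycle(g)
  if (!is.null(cyc)) {
    stop("is_a cycle detected involving term ", cyc)
  }
  g
}

# Kahn's algorithm; returns a term on a cycle, or NULL if acyclic.
find_isa_cycle <- function(graph) {
  ids <- names(graph$classes)
  outdeg <- vapply(ids, function(t) {
    length(graph$isa_parents[[t]])
  }, integer(1L))
  names(outdeg) <- ids
  children <- new.env(parent = emptyenv())
  for (child in names(graph$isa_parents)) {
    for (p in graph$isa_parents[[child]]) {
      children[[p]] <- c(children[[p]], child)
    }
  }
  queue <- ids[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) names(outdeg)[outdeg > 0L][[1L]] else NULL
}

#' @export
print.eqsim_graph <- function(x, ...) {
  n_obs <- sum(vapply(x$classes, function(cl) isTRUE(cl$obsolete), logical(1L)))
  cat("<ontology graph> ", length(x$classes), " classes (",
      n_obs, " obsolete), ",
      sum(lengths(x$isa_parents)), " is_a edges, ",
      nrow(x$rel_edges), " relationship edges, ",
      length(x$properties), " properties\n", sep = "")
  invisible(x)
}

#' Resolve an ontology label or synonym to a term id
#'
#' Exact label matches win; synonyms are consulted only when no label
#' matches.  Obsolete classes are never returned.  Ambiguity (two
#' classes sharing the label) is an error, as is an unknown label, which
#' reports near matches to aid curation.
#'
#' @param graph An `eqsim_graph`.
#' @param label Label text.
#' @return A term id string.
#' @export
resolve_label <- function(graph, label) {
  live <- names(graph$classes)[!vapply(graph$classes, function(cl)
    isTRUE(cl$obsolete), logical(1L))]
  labs <- vapply(graph$classes[live], function(cl)
    if (is.null(cl$label)) NA_character_ else cl$label, character(1L))
  hit <- live[!is.na(labs) & labs == label]
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L) {
    stop("ambiguous label '", label, "': ", paste(hit, collapse = ", "))
  }
  syn_hit <- live[vapply(graph$classes[live], function(cl)
    label %in% cl$synonyms, logical(1L))]
  if (length(syn_hit) == 1L) return(syn_hit)
  if (length(syn_hit) > 1L) {
    stop("ambiguous synonym '", label, "': ", paste(syn_hit, collapse = ", "))
  }
  near <- live[!is.na(labs) & agrepl(label, labs, max.distance = 0.3)]
  stop("cannot resolve label '", label, "'",
       if (length(near)) paste0("; near matches: ",
                                paste(utils::head(labs[match(near, live)], 5L),
                                      collapse = ", ")) else "")
}

#' Parse an OBO 1.2/1.4 flat file
#'
#' Reads the fragment of the OBO format needed here: `[Term]` stanzas
#' (tags `id`, `name`, `synonym`, `is_a`, `relationship`, `is_obsolete`)
#' and `[Typedef]` stanzas (`id`, `is_transitive`).  `intersection_of`
#' and `equivalent_to` lines are outside the supported fragment and are
#' ignored with a warning.  Obsolete terms are kept but flagged.  A
#' cycle in `is_a`, or an edge to an undeclared term, is a load error.
#'
#' @param con Path to an OBO file, or a character vector of its lines.
#' @return An `eqsim_graph`.
#' @export
parse_obo <- function(con) {
  lines <- if (length(con) == 1L && file.exists(con)) readLines(con, warn = FALSE)
           else as.character(con)
  classes <- list()
  isa_parents <- list()
  rel_subj <- character(0); rel_prop <- character(0); rel_obj <- character(0)
  properties <- list()
  ignored_tags <- character(0)

  stanza <- NULL       # "Term" | "Typedef" | other
  cur <- NULL
  cur_line <- NA_integer_

  flush_stanza <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop("stanza starting at line ", cur_line, " has no id tag")
    }
    if (identical(stanza, "Term")) {
      classes[[cur$id]] <<- list(label = cur$label,
                                 synonyms = cur$synonyms %||% character(0),
                                 obsolete = isTRUE(cur$obsolete))
      if (length(cur$isa)) isa_parents[[cur$id]] <<- unique(cur$isa)
      if (length(cur$rel_prop)) {
        rel_subj <<- c(rel_subj, rep(cur$id, length(cur$rel_prop)))
        rel_prop <<- c(rel_prop, cur$rel_prop)
        rel_obj  <<- c(rel_obj, cur$rel_obj)
      }
    } else if (identical(stanza, "Typedef")) {
      properties[[cur$id]] <<- list(transitive = isTRUE(cur$transitive))
    }
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])   # strip OBO comments
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush_stanza()
      stanza <- sub("^\\[(.*)\\]$", "\\1", line)
      cur <- list()
      cur_line <- i
      next
    }
    if (is.null(cur)) next                # header tags (format-version etc.)
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(m) != 3L) stop("malformed line ", i, ": ", lines[[i]])
    tag <- m[[2L]]; val <- trimws(m[[3L]])
    if (!stanza %in% c("Term", "Typedef")) next
    switch(tag,
      id = { cur$id <- val },
      name = { cur$label <- val },
      synonym = {
        sm <- regmatches(val, regexec("^\"(.*)\"", val))[[1L]]
        if (length(sm) == 2L) cur$synonyms <- c(cur$synonyms, sm[[2L]])
      },
      is_a = { cur$isa <- c(cur$isa, sub("\\s.*$", "", val)) },
      relationship = {
        parts <- strsplit(val, "\\s+")[[1L]]
        if (length(parts) < 2L) stop("malformed relationship at line ", i)
        cur$rel_prop <- c(cur$rel_prop, parts[[1L]])
        cur$rel_obj  <- c(cur$rel_obj, parts[[2L]])
      },
      is_obsolete = { cur$obsolete <- identical(val, "true") },
      is_transitive = { cur$transitive <- identical(val, "true") },
      intersection_of = ,
      equivalent_to = { ignored_tags <- c(ignored_tags, tag) },
      NULL)
  }
  flush_stanza()

  if (length(ignored_tags)) {
    warning("ignored ", length(ignored_tags), " line(s) outside the supported ",
            "OBO fragment: ", paste(unique(ignored_tags), collapse = ", "))
  }
  # properties referenced by relationship lines but never declared get an
  # implicit non-transitive declaration (common in OBO slices)
  for (p in setdiff(unique(rel_prop), names(properties))) {
    properties[[p]] <- list(transitive = FALSE)
  }
  ontology_graph(classes, isa_parents,
                 data.frame(subject = rel_subj, property = rel_prop,
                            object = rel_obj, stringsAsFactors = FALSE),
                 properties)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge ontology graphs into one comprehensive ontology
#'
#' Class sets, `is_a` edges, relationship edges and property
#' declarations are unioned.  A term id appearing in several graphs
#' collapses to one class; on a label conflict the first graph's label
#' is kept and a warning is issued.  A property is transitive in the
#' merge if any input declares it transitive.
#'
#' @param graphs Non-empty list of `eqsim_graph` objects.
#' @return A single `eqsim_graph`.
#' @export
merge_ontologies <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  classes <- list(); isa <- list(); props <- list()
  rels <- list()
  conflicts <- character(0)
  for (g in graphs) {
    stopifnot(inherits(g, "eqsim_graph"))
    for (id in names(g$classes)) {
      if (is.null(classes[[id]])) {
        classes[[id]] <- g$classes[[id]]
      } else {
        old <- classes[[id]]; new <- g$classes[[id]]
        if (!is.null(old$label) && !is.null(new$label) &&
            !identical(old$label, new$label)) {
          conflicts <- c(conflicts, id)
        }
        classes[[id]]$synonyms <- union(old$synonyms, new$synonyms)
        classes[[id]]$obsolete <- old$obsolete || isTRUE(new$obsolete)
      }
    }
    for (ch in names(g$isa_parents)) {
      isa[[ch]] <- union(isa[[ch]], g$isa_parents[[ch]])
    }
    rels[[length(rels) + 1L]] <- g$rel_edges
    for (p in names(g$properties)) {
      props[[p]] <- list(transitive = isTRUE(props[[p]]$transitive) ||
                           isTRUE(g$properties[[p]]$transitive))
    }
  }
  if (length(conflicts)) {
    warning("label conflict for ", length(unique(conflicts)),
            " term(s); first graph's label kept: ",
            paste(unique(conflicts), collapse = ", "))
  }
  rel <- unique(do.call(rbind, rels))
  rownames(rel) <- NULL
  ontology_graph(classes, isa, rel, props)
}

#' Enumerate existential-restriction classes over an ontology
#'
#' Returns the vocabulary of `OP some U` expressions for every
#' non-obsolete class `U` and every listed object property `OP` —
#' the expression-level subsumer vocabulary added to the comprehensive
#' ontology so reasoning can traverse post-composition dimensions such
#' as `part_of`.  The graph itself is not mutated.
#'
#' @param graph An `eqsim_graph`.
#' @param properties Character vector of property names declared in
#'   `graph`.
#' @return A list of `eqsim_expr` objects (possibly empty), one per
#'   class/property pair.
#' @export
augment_with_existentials <- function(graph, properties) {
  stopifnot(inherits(graph, "eqsim_graph"))
  bad <- setdiff(properties, names(graph$properties))
  if (length(bad)) stop("unknown object property: ", paste(bad, collapse = ", "))
  live <- names(graph$classes)[!vapply(graph$classes, function(cl)
    isTRUE(cl$obsolete), logical(1L))]
  out <- list()
  for (p in properties) {
    for (u in live) out[[length(out) + 1L]] <- expr_some(p, expr_named(u))
  }
  out
}

#' Write an ontology graph to an OBO flat file
#'
#' Emits the same fragment [parse_obo()] reads, so a graph round-trips
#' through disk.  Used by the synthetic-data CLI.
#'
#' @param graph An `eqsim_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2", "")
  for (id in names(graph$classes)) {
    cl <- graph$classes[[id]]
    out <- c(out, "[Term]", paste0("id: ", id))
    if (!is.null(cl$label)) out <- c(out, paste0("name: ", cl$label))
    for (s in cl$synonyms) {
      out <- c(out, paste0("synonym: \"", s, "\" EXACT []"))
    }
    for (p in graph$isa_parents[[id]]) out <- c(out, paste0("is_a: ", p))
    re <- graph$rel_edges[graph$rel_edges$subject == id, , drop = FALSE]
    for (k in seq_len(nrow(re))) {
      out <- c(out, paste0("relationship: ", re$property[[k]], " ",
                           re$object[[k]]))
    }
    if (isTRUE(cl$obsolete)) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  for (p in names(graph$properties)) {
    out <- c(out, "[Typedef]", paste0("id: ", p))
    if (isTRUE(graph$properties[[p]]$transitive)) {
      out <- c(out, "is_transitive: true")
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
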