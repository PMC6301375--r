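#' EQ annotations
#'
#' An EQ annotation describes a phenotype as an Entity (typically an
#' anatomical structure) bearing a Quality, optionally relative to a
#' Related Entity (e.g. `in contact with` some other bone).  Each slot
#' is a class expression — a named ontology term or a post-composition.
#' An annotation is *complete* iff entity and quality are both present
#' and every term in every slot resolves in the working ontology;
#' incomplete annotations are retained (with their raw text) because
#' state-level scoring must see them — any character state containing
#' one scores zero on every metric.
#'
#' @param entity,quality,related_entity Class expressions, given as
#'   `eqsim_expr` objects or as post-composition strings to be parsed
#'   against `graph`; `NULL` for absent slots.
#' @param graph An `eqsim_graph` used for parsing/resolution, or `NULL`
#'   to accept pre-built expressions unchecked.
#' @return An object of class `eqsim_eq` with fields `entity`,
#'   `quality`, `related_entity`, `complete`, and `raw` (original text
#'   for any slot that failed to parse).
#' @export
eq_annotation <- function(entity = NULL, quality = NULL,
                          related_entity = NULL, graph = NULL) {
  slot_parse <- function(x) {
    if (is.null(x) || (is.character(x) && !nzchar(trimws(x)))) {
      return(list(expr = NULL, raw = NULL, ok = TRUE))
    }
    if (inherits(x, "eqsim_expr")) {
      if (!is.null(graph)) {
        bad <- setdiff(expr_terms(x), names(graph$classes))
        if (length(bad)) return(list(expr = NULL, raw = render_expr(x),
                                     ok = FALSE))
      }
      return(list(expr = x, raw = NULL, ok = TRUE))
    }
    out <- tryCatch(list(expr = parse_expression(x, graph), raw = NULL,
                         ok = TRUE),
                    error = function(e) list(expr = NULL, raw = as.character(x),
                                             ok = FALSE))
    out
  }
  e <- slot_parse(entity); q <- slot_parse(quality); r <- slot_parse(related_entity)
  complete <- !is.null(e$expr) && !is.null(q$expr) && e$ok && q$ok && r$ok
  raw <- list(entity = e$raw, quality = q$raw, related_entity = r$raw)
  structure(list(entity = e$expr, quality = q$expr,
                 related_entity = r$expr, complete = complete, raw = raw),
            class = "eqsim_eq")
}

#' Canonical rendering of an EQ annotation
#'
#' Renders the three slots in a fixed `E= Q= RE=` layout; used as the
#' identity key in annotation corpora and caches.  Unparsed slots fall
#' back to their raw text prefixed with `!`.
#'
#' @param eq An `eqsim_eq`.
#' @return A single string.
#' @export
eq_render <- function(eq) {
  slot <- function(expr, raw) {
    if (!is.null(expr)) render_expr(expr)
    else if (!is.null(raw)) paste0("!", raw)
    else "-"
  }
  paste0("E=", slot(eq$entity, eq$raw$entity),
         " Q=", slot(eq$quality, eq$raw$quality),
         " RE=", slot(eq$related_entity, eq$raw$related_entity))
}

#' @export
format.eqsim_eq <- function(x, ...) eq_render(x)

#' @export
print.eqsim_eq <- function(x, ...) {
  cat("<EQ annotation", if (!x$complete) " (incomplete)", "> ",
      eq_render(x), "\n", sep = "")
  invisible(x)
}

#' A character state and its annotations
#'
#' A character state is one alternative condition of a phylogenetic
#' character (e.g. "pectoral fin: absent"); it carries zero or more EQ
#' annotations.  `(study, character_id, state_id)` is the state key,
#' unique within an annotation source.
#'
#' @param study,character_id,state_id Key components.
#' @param character_text,state_text Free-text descriptions.
#' @param annotations List of `eqsim_eq`.
#' @return An object of class `eqsim_state`.
#' @export
character_state <- function(study, character_id, state_id,
                            character_text = "", state_text = "",
                            annotations = list()) {
  stopifnot(all(vapply(annotations, inherits, logical(1L), "eqsim_eq")))
  structure(list(study = study, character_id = character_id,
                 state_id = state_id, character_text = character_text,
                 state_text = state_text, annotations = annotations),
            class = "eqsim_state")
}

state_key <- function(state) {
  paste(state$study, state$character_id, state$state_id, sep = "\r")
}

#' An annotation source (one curator, machine run, or gold standard)
#'
#' @param source_id Short label, e.g. `"C1"`, `"SCP"`, `"GOLD"`.
#' @param states List of `eqsim_state` (keys must be unique).
#' @param round Optional curation-round label.
#' @param ontology_id Optional label of the ontology version used.
#' @return An object of class `eqsim_source`; states are stored in a
#'   named list keyed by the state key, sorted lexicographically.
#' @export
annotation_source <- function(source_id, states = list(), round = NULL,
                              ontology_id = NULL) {
  keys <- vapply(states, state_key, character(1L))
  if (anyDuplicated(keys)) {
    stop("duplicate state key in source ", source_id, ": ",
         keys[duplicated(keys)][[1L]])
  }
  names(states) <- keys
  states <- states[order(keys, method = "radix")]
  structure(list(source_id = source_id, round = round,
                 ontology_id = ontology_id, states = states),
            class = "eqsim_source")
}

#' @export
print.eqsim_source <- function(x, ...) {
  n_eq <- sum(vapply(x$states, function(s) length(s$annotations), integer(1L)))
  cat("<annotation source '", x$source_id, "'> ", length(x$states),
      " character states, ", n_eq, " EQ annotations\n", sep = "")
  invisible(x)
}

ann_columns <- c("study", "character_id", "state_id", "character_text",
                 "state_text", "entity", "quality", "related_entity")

#' Read an annotation table
#'
#' The interchange format is a UTF-8 tab-delimited table with a header
#' row and columns `study`, `character_id`, `state_id`,
#' `character_text`, `state_text`, `entity`, `quality`,
#' `related_entity` — one row per EQ annotation; rows sharing a state
#' key accumulate annotations on that state; a row with all three
#' expression columns blank declares an unannotated state.  Expressions
#' use the post-composition grammar of [parse_expression()].  Rows
#' whose expressions fail to resolve yield incomplete annotations with
#' the raw text preserved.
#'
#' @param path Path to the TSV file (or a character vector of lines).
#' @param graph An `eqsim_graph` for expression resolution.
#' @param source_id Label for the resulting source; defaults to the
#'   file name.
#' @return An `eqsim_source`.
#' @export
read_annotations <- function(path, graph, source_id = NULL) {
  if (length(path) == 1L && file.exists(path)) {
    df <- utils::read.delim(path, colClasses = "character", quote = "",
                            check.names = FALSE, na.strings = NULL)
    if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  } else {
    df <- utils::read.delim(text = paste(path, collapse = "\n"),
                            colClasses = "character", quote = "",
                            check.names = FALSE, na.strings = NULL)
    if (is.null(source_id)) source_id <- "source"
  }
  missing_cols <- setdiff(ann_columns, names(df))
  if (length(missing_cols)) {
    stop("annotation table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  states <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    key <- paste(row$study, row$character_id, row$state_id, sep = "\r")
    st <- states[[key]]
    if (is.null(st)) {
      st <- character_state(row$study, row$character_id, row$state_id,
                            row$character_text, row$state_text)
    }
    has_eq <- any(nzchar(trimws(c(row$entity, row$quality,
                                  row$related_entity))))
    if (has_eq) {
      eq <- eq_annotation(row$entity, row$quality, row$related_entity, graph)
      st$annotations <- c(st$annotations, list(eq))
    }
    states[[key]] <- st
  }
  annotation_source(source_id, unname(states))
}

#' Write an annotation source to the interchange TSV
#'
#' Inverse of [read_annotations()]: round-trips a source exactly
#' (incomplete slots are written back as their raw text).
#'
#' @param source An `eqsim_source`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(source, path) {
  rows <- list()
  slot_text <- function(expr, raw) {
    if (!is.null(expr)) render_expr(expr) else if (!is.null(raw)) raw else ""
  }
  for (st in source$states) {
    anns <- st$annotations
    if (!length(anns)) {
      rows[[length(rows) + 1L]] <- c(st$study, st$character_id, st$state_id,
                                     st$character_text, st$state_text,
                                     "", "", "")
    }
    for (eq in anns) {
      rows[[length(rows) + 1L]] <-
        c(st$study, st$character_id, st$state_id, st$character_text,
          st$state_text,
          slot_text(eq$entity, eq$raw$entity),
          slot_text(eq$quality, eq$raw$quality),
          slot_text(eq$related_entity, eq$raw$related_entity))
    }
  }
  mat <- do.call(rbind, c(list(ann_columns), rows))
  writeLines(apply(mat, 1L, paste, collapse = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Validate an annotation source against curation conventions
#'
#' Flags, per state: `INCOMPLETE_EQ` (an annotation whose expressions
#' did not fully resolve), `EMPTY_STATE` (no annotations),
#' `RELATIONAL_Q_WITHOUT_RE` (a relational quality such as *in contact
#' with*, which needs a related entity, used without one), and
#' `OBSOLETE_TERM` (an annotation using an obsolete class).  Validation
#' reports issues; it never throws on content.
#'
#' @param source An `eqsim_source`.
#' @param graph An `eqsim_graph`.
#' @param relational_qualities Character vector of quality term ids
#'   that require a related entity.
#' @return A data frame with columns `study`, `character_id`,
#'   `state_id`, `issue`, `detail` (zero rows for a clean source).
#' @export
validate_annotations <- function(source, graph,
                                 relational_qualities = character(0)) {
  issues <- list()
  note <- function(st, issue, detail = "") {
    issues[[length(issues) + 1L]] <<-
      data.frame(study = st$study, character_id = st$character_id,
                 state_id = st$state_id, issue = issue, detail = detail,
                 stringsAsFactors = FALSE)
  }
  for (st in source$states) {
    if (!length(st$annotations)) {
      note(st, "EMPTY_STATE")
      next
    }
    for (eq in st$annotations) {
      if (!eq$complete) {
        raw <- unlist(eq$raw)
        note(st, "INCOMPLETE_EQ", paste(raw, collapse = "; "))
        next
      }
      terms <- unique(c(expr_terms(eq$entity), expr_terms(eq$quality),
                        if (!is.null(eq$related_entity))
                          expr_terms(eq$related_entity)))
      obs <- terms[vapply(terms, function(t)
        isTRUE(graph$classes[[t]]$obsolete), logical(1L))]
      if (length(obs)) note(st, "OBSOLETE_TERM", paste(obs, collapse = ", "))
      q_terms <- expr_terms(eq$quality)
      if (length(intersect(q_terms, relational_qualities)) &&
          is.null(eq$related_entity)) {
        note(st, "RELATIONAL_Q_WITHOUT_RE",
             paste(intersect(q_terms, relational_qualities), collapse = ", "))
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(study = character(0), character_id = character(0),
                      state_id = character(0), issue = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
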