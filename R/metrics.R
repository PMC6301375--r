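#' Jaccard similarity between two EQ annotations
#'
#' The ratio of shared to total subsumers,
#' `|S(N1) n S(N2)| / |S(N1) u S(N2)|`, where `S(N)` is the full
#' subsumer universe of the annotation (E–Q–RE triples plus combined
#' class-expression superclasses, see [subsumers()]).  Equal to 1 for
#' identical annotations and 0 when they share no subsumer.
#'
#' @param eq1,eq2 Complete `eqsim_eq` annotations.
#' @param graph An `eqsim_graph`.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(eq1, eq2, graph) {
  s1 <- subsumers(eq1, graph)$keys
  s2 <- subsumers(eq2, graph)$keys
  n_int <- length(intersect(s1, s2))
  if (n_int == 0L) return(0)
  n_int / length(union(s1, s2))
}

#' Build an annotation corpus for information-content scoring
#'
#' Tallies how often each distinct EQ annotation (by canonical
#' rendering) occurs across the given sources.  The usual corpus is
#' every human annotation round plus the machine annotations, so that
#' node probabilities reflect the whole study.  Incomplete annotations
#' have no node in the EQ graph and are excluded from the counts (the
#' number excluded is recorded).
#'
#' @param sources List of `eqsim_source` objects.
#' @return An object of class `eqsim_corpus`: fields `counts` (named
#'   integer vector keyed by EQ rendering), `eqs` (named list of one
#'   representative `eqsim_eq` per key), `total`, `n_incomplete`.
#' @export
build_corpus <- function(sources) {
  if (inherits(sources, "eqsim_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1L)
  counts <- integer(0)
  eqs <- list()
  n_incomplete <- 0L
  for (src in sources) {
    for (st in src$states) {
      for (eq in st$annotations) {
        if (!eq$complete) { n_incomplete <- n_incomplete + 1L; next }
        key <- eq_render(eq)
        if (is.null(eqs[[key]])) {
          eqs[[key]] <- eq
          counts[[key]] <- 1L
        } else {
          counts[[key]] <- counts[[key]] + 1L
        }
      }
    }
  }
  structure(list(counts = counts, eqs = eqs, total = sum(counts),
                 n_incomplete = n_incomplete),
            class = "eqsim_corpus")
}

#' @export
print.eqsim_corpus <- function(x, ...) {
  cat("<annotation corpus> ", length(x$counts), " distinct EQ nodes, ",
      x$total, " annotations (", x$n_incomplete, " incomplete excluded)\n",
      sep = "")
  invisible(x)
}

# If expr is the combined form And(Q, inheres_in some E[, towards some RE]),
# return its equivalent E-Q-RE triple of renderings, else NULL.  The
# combined expression and the identity triple denote the same node of the
# ad hoc EQ graph; IC and LCS work on nodes, so the two encodings are
# identified there (they stay distinct as set elements for Jaccard).
expr_to_triple <- function(expr) {
  if (expr$kind != "and") return(NULL)
  e <- NULL; re <- NULL; q <- NULL
  for (a in expr$args) {
    if (a$kind == "some" && a$property == "inheres_in") {
      if (!is.null(e)) return(NULL)
      e <- a$filler
    } else if (a$kind == "some" && a$property == "towards") {
      if (!is.null(re)) return(NULL)
      re <- a$filler
    } else {
      if (!is.null(q)) return(NULL)
      q <- a
    }
  }
  if (is.null(e) || is.null(q)) return(NULL)
  list(e = e, q = q, re = re)
}

# Canonical node key for an IC/LCS node: an eqsim_eq, an eqsim_expr, a
# triple list(e=, q=, re=) of eqsim_expr, or an already-tagged key string.
ic_node_key <- function(node) {
  if (is.character(node)) {
    if (startsWith(node, "X:")) {
      expr <- parse_expression(substring(node, 3L), NULL)
      tri <- expr_to_triple(expr)
      if (!is.null(tri)) {
        return(triple_key(render_expr(tri$e), render_expr(tri$q),
                          if (is.null(tri$re)) NULL else render_expr(tri$re)))
      }
    }
    return(node)
  }
  if (inherits(node, "eqsim_eq")) {
    if (!node$complete) stop("an incomplete EQ has no node in the EQ graph")
    return(triple_key(render_expr(node$entity), render_expr(node$quality),
                      if (is.null(node$related_entity)) NULL
                      else render_expr(node$related_entity)))
  }
  if (inherits(node, "eqsim_expr")) {
    tri <- expr_to_triple(node)
    if (!is.null(tri)) {
      return(triple_key(render_expr(tri$e), render_expr(tri$q),
                        if (is.null(tri$re)) NULL else render_expr(tri$re)))
    }
    return(paste0("X:", render_expr(node)))
  }
  if (is.list(node) && !is.null(node$e)) {
    return(triple_key(render_expr(node$e), render_expr(node$q),
                      if (is.null(node$re)) NULL else render_expr(node$re)))
  }
  stop("cannot interpret node for information content")
}

# Membership key sets of every corpus EQ, with And-shape expression
# elements canonicalized to their triple key; memoized on the corpus
# via an environment captured in the graph cache.
corpus_membership <- function(corpus, graph) {
  cache <- graph$cache
  if (is.null(cache$corpus_keys)) {
    cache$corpus_keys <- new.env(parent = emptyenv())
  }
  tag <- paste0(length(corpus$counts), ":", corpus$total)
  hit <- cache$corpus_keys[[tag]]
  if (!is.null(hit) && identical(hit$names, names(corpus$counts))) {
    return(hit$sets)
  }
  sets <- lapply(corpus$eqs, function(eq) {
    keys <- subsumers(eq, graph)$keys
    xk <- keys[startsWith(keys, "X:")]
    canon <- vapply(xk, ic_node_key, character(1L))
    unique(c(keys, canon))
  })
  cache$corpus_keys[[tag]] <- list(names = names(corpus$counts), sets = sets)
  sets
}

ic_value <- function(node_key, corpus, graph) {
  if (corpus$total <= 0L) stop("corpus has no annotations")
  sets <- corpus_membership(corpus, graph)
  f <- sum(corpus$counts[vapply(sets, function(s) node_key %in% s,
                                logical(1L))])
  imax <- log(corpus$total)
  if (f == 0L) {
    return(list(I = imax, In = 1, p = 0))
  }
  p <- f / corpus$total
  i <- -log(p)
  list(I = i, In = if (p == 1) 0 else if (imax > 0) i / imax else 0, p = p)
}

#' Information content of a node in the EQ annotation graph
#'
#' The probability of a node is the fraction of corpus annotations made
#' to the node or to any node it subsumes; its information content is
#' `I = -log p` (natural log), normalized as `In = I / Imax` with
#' `Imax = -log(1 / total)` so that `In` lies in `[0, 1]` (and is 0
#' when `p = 1`).  A node that subsumes no annotated node has `p = 0`;
#' it is assigned the bounded maximum `I = Imax`, `In = 1`, with a
#' note.
#'
#' @param node An `eqsim_eq`, an `eqsim_expr` subsumer, or a tagged
#'   subsumer key as found in [subsumers()]`$keys`.
#' @param corpus An `eqsim_corpus` with `total > 0`.
#' @param graph An `eqsim_graph`.
#' @return A list with components `I` (nats), `In` (normalized, in
#'   `[0,1]`) and `p`.
#' @export
information_content <- function(node, corpus, graph) {
  out <- ic_value(ic_node_key(node), corpus, graph)
  if (out$p == 0) {
    message("node subsumes no annotated node; assigned I = Imax, In = 1")
  }
  out
}

# ---- least common subsumer ---------------------------------------------

# Structured view of a common-subsumer node key.
node_struct <- function(key, graph) {
  if (startsWith(key, "T:")) {
    parts <- strsplit(substring(key, 3L), "\x1f", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) parts <- c(parts, "")
    list(kind = "T",
         e = parse_expression(parts[[1L]], graph),
         q = parse_expression(parts[[2L]], graph),
         re = if (nzchar(parts[[3L]])) parse_expression(parts[[3L]], graph))
  } else {
    list(kind = "X", expr = parse_expression(substring(key, 3L), graph))
  }
}

node_subsumes <- function(graph, a, b) {
  # does node a subsume node b? (same-kind comparisons only)
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "T") {
    if (is.null(a$re) != is.null(b$re)) return(FALSE)
    expr_subsumes(graph, a$e, b$e) && expr_subsumes(graph, a$q, b$q) &&
      (is.null(a$re) || expr_subsumes(graph, a$re, b$re))
  } else {
    expr_subsumes(graph, a$expr, b$expr)
  }
}

#' Normalized information content of the least common subsumer
#'
#' The common subsumers of two annotations are the intersection of
#' their subsumer universes; a least common subsumer (LCS) is a common
#' subsumer that does not strictly subsume another common subsumer.
#' When several LCS candidates exist the one with the highest
#' information content is used (ties broken lexicographically on the
#' canonical key, for deterministic reports).  Returns that node's
#' `In`, or 0 when the annotations share no subsumer.
#'
#' @param eq1,eq2 Complete `eqsim_eq` annotations.
#' @param corpus An `eqsim_corpus`.
#' @param graph An `eqsim_graph`.
#' @return A number in `[0, 1]`.
#' @export
lcs_similarity <- function(eq1, eq2, corpus, graph) {
  graph <- ensure_eq_properties(graph)
  common <- intersect(subsumers(eq1, graph)$keys, subsumers(eq2, graph)$keys)
  if (!length(common)) return(0)
  # identify equivalent encodings (combined expression == identity triple)
  canon <- vapply(common, ic_node_key, character(1L))
  common <- common[!duplicated(canon)]
  canon <- canon[!duplicated(canon)]
  structs <- lapply(common, node_struct, graph = graph)
  k <- length(structs)
  minimal <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || !minimal[[i]]) next
      if (node_subsumes(graph, structs[[i]], structs[[j]])) {
        minimal[[i]] <- FALSE
        break
      }
    }
  }
  cand_keys <- canon[minimal]
  ics <- vapply(cand_keys, function(nk) ic_value(nk, corpus, graph)$I,
                numeric(1L))
  best <- which(ics == max(ics))
  if (length(best) > 1L) {
    best <- best[order(cand_keys[best], method = "radix")][[1L]]
  }
  ic_value(cand_keys[[best]], corpus, graph)$In
}

#' Partial precision and partial recall between annotation lists
#'
#' Directional state-level scores comparing a test curator's
#' annotations against a reference curator's: partial precision is the
#' mean, over test annotations, of each one's best Jaccard similarity
#' to any reference annotation; partial recall is the mean, over
#' reference annotations, of each one's best similarity to any test
#' annotation.  Extra dissimilar test annotations lower PP; reference
#' annotations the test curator missed lower PR.  The two are
#' transposes: `PP(R, T) == PR(T, R)`.
#'
#' @param ref_eqs,test_eqs Non-empty lists of complete `eqsim_eq`.
#' @param graph An `eqsim_graph`.
#' @return A list with components `PP` and `PR`, both in `[0, 1]`.
#' @export
partial_scores <- function(ref_eqs, test_eqs, graph) {
  if (!length(ref_eqs) || !length(test_eqs)) {
    stop("partial_scores needs non-empty annotation lists ",
         "(empty states take the state-level zero rule)")
  }
  jmat <- matrix(0, nrow = length(ref_eqs), ncol = length(test_eqs))
  for (i in seq_along(ref_eqs)) {
    for (j in seq_along(test_eqs)) {
      jmat[i, j] <- jaccard(ref_eqs[[i]], test_eqs[[j]], graph)
    }
  }
  list(PP = mean(apply(jmat, 2L, max)),
       PR = mean(apply(jmat, 1L, max)))
}

EQ_METRICS <- c("PP", "PR", "JSIM", "IN")

#' Similarity of two curations of one character state
#'
#' Best-match aggregation at the state level: for `JSIM` and `IN` the
#' score is the maximum pairwise value over all reference x test
#' annotation pairs; `PP` and `PR` come from [partial_scores()].  If
#' either curation of the state contains an incomplete annotation, or
#' has no annotations at all, the state scores 0 and is flagged — a
#' comparison against unresolvable content carries no semantic credit.
#'
#' @param ref_state,test_state `eqsim_state` objects sharing a key.
#' @param metric One of `"PP"`, `"PR"`, `"JSIM"`, `"IN"`.
#' @param graph An `eqsim_graph`.
#' @param corpus An `eqsim_corpus` (required for `"IN"`).
#' @return One-row data frame: `study`, `character_id`, `state_id`,
#'   `metric`, `value`, `n_ref_eqs`, `n_test_eqs`, `zeroed`.
#' @export
state_similarity <- function(ref_state, test_state, metric, graph,
                             corpus = NULL) {
  metric <- match.arg(metric, EQ_METRICS)
  if (!identical(state_key(ref_state), state_key(test_state))) {
    stop("state keys differ: ", state_key(ref_state), " vs ",
         state_key(test_state))
  }
  refs <- ref_state$annotations
  tests <- test_state$annotations
  incomplete <- any(!vapply(refs, function(e) e$complete, logical(1L))) ||
    any(!vapply(tests, function(e) e$complete, logical(1L)))
  empty <- length(refs) == 0L || length(tests) == 0L
  row <- data.frame(study = ref_state$study,
                    character_id = ref_state$character_id,
                    state_id = ref_state$state_id,
                    metric = metric, value = 0,
                    n_ref_eqs = length(refs), n_test_eqs = length(tests),
                    zeroed = FALSE, stringsAsFactors = FALSE)
  if (incomplete || empty) {
    row$zeroed <- TRUE
    return(row)
  }
  row$value <- switch(metric,
    PP = partial_scores(refs, tests, graph)$PP,
    PR = partial_scores(refs, tests, graph)$PR,
    JSIM = {
      best <- 0
      for (r in refs) for (t in tests) {
        best <- max(best, jaccard(r, t, graph))
      }
      best
    },
    IN = {
      if (is.null(corpus)) stop("metric IN needs an annotation corpus")
      best <- 0
      for (r in refs) for (t in tests) {
        best <- max(best, lcs_similarity(r, t, corpus, graph))
      }
      best
    })
  row
}

#' Similarity between two annotation sources
#'
#' Computes state-level scores over the character states the two
#' sources share and averages them into one consistency score per
#' metric.  States present in only one source are excluded from the
#' mean and reported in the attributes (`n_only_ref`, `n_only_test`).
#' With `empty_policy = "zero"` (default) a shared state that either
#' source left unannotated scores 0 and enters the mean; with
#' `"exclude"` such states are reported but kept out of the mean.
#'
#' @param ref,test `eqsim_source` objects sharing at least one state.
#' @param metrics Character vector from `"PP"`, `"PR"`, `"JSIM"`,
#'   `"IN"`; all four by default.
#' @param graph An `eqsim_graph`.
#' @param corpus An `eqsim_corpus` (needed when `"IN"` is requested);
#'   defaults to a corpus built from `ref` and `test`.
#' @param empty_policy `"zero"` or `"exclude"`.
#' @return A list with `per_state` (data frame, one row per shared
#'   state and metric, sorted by state key; column `in_mean` marks the
#'   rows entering the mean), and `summary` (data frame with one row
#'   per metric: `mean`, `sem`, `n_states`).
#' @export
source_similarity <- function(ref, test, metrics = EQ_METRICS, graph,
                              corpus = NULL,
                              empty_policy = c("zero", "exclude")) {
  empty_policy <- match.arg(empty_policy)
  metrics <- match.arg(metrics, EQ_METRICS, several.ok = TRUE)
  shared <- intersect(names(ref$states), names(test$states))
  if (!length(shared)) {
    stop("sources ", ref$source_id, " and ", test$source_id,
         " share no character state")
  }
  shared <- sort(shared, method = "radix")
  if (is.null(corpus) && "IN" %in% metrics) {
    corpus <- build_corpus(list(ref, test))
  }
  rows <- list()
  for (key in shared) {
    for (m in metrics) {
      r <- state_similarity(ref$states[[key]], test$states[[key]], m,
                            graph, corpus)
      empty <- r$n_ref_eqs == 0L || r$n_test_eqs == 0L
      r$in_mean <- !(empty && empty_policy == "exclude")
      rows[[length(rows) + 1L]] <- r
    }
  }
  per_state <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_state$value[per_state$metric == m & per_state$in_mean]
    data.frame(metric = m, mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               n_states = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(per_state = per_state, summary = summ),
            n_only_ref = length(setdiff(names(ref$states), shared)),
            n_only_test = length(setdiff(names(test$states), shared)),
            class = "eqsim_comparison")
}

#' @export
print.eqsim_comparison <- function(x, ...) {
  cat("<source comparison> ", length(unique(paste(x$per_state$study,
      x$per_state$character_id, x$per_state$state_id))),
      " shared states\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
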