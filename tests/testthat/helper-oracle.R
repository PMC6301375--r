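# Independent brute-force reference implementations.  These deliberately
# avoid the package's subsumption engine: named-class reachability is an
# adjacency-matrix closure, expression superclasses are enumerated by
# plain recursion without caching, and the metrics are computed by naive
# set operations on rendered strings.  Shared by the test suite and the
# acceptance script.

oracle_ancestors <- function(graph, term) {
  ids <- names(graph$classes)
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (ch in names(graph$isa_parents)) {
    adj[ch, graph$isa_parents[[ch]]] <- TRUE
  }
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  obsolete <- vapply(graph$classes, function(cl) isTRUE(cl$obsolete),
                     logical(1L))
  anc <- ids[reach[term, ] & !obsolete]
  sort(anc)
}

oracle_render <- function(x) {
  switch(x$kind,
    named = x$term,
    some  = paste0("(", x$property, " some ", oracle_render(x$filler), ")"),
    and   = paste0("(", paste(sort(vapply(x$args, oracle_render,
                                          character(1L)), method = "radix"),
                              collapse = " and "), ")"))
}

oracle_sup_structs <- function(graph, expr) {
  if (expr$kind == "named") {
    return(lapply(oracle_ancestors(graph, expr$term), expr_named))
  }
  if (expr$kind == "some") {
    p <- expr$property
    acc <- list()
    seen <- character(0)
    add <- function(e) {
      k <- oracle_render(e)
      if (!k %in% seen) {
        seen <<- c(seen, k)
        acc[[length(acc) + 1L]] <<- e
        TRUE
      } else FALSE
    }
    for (f in oracle_sup_structs(graph, expr$filler)) add(expr_some(p, f))
    if (isTRUE(graph$properties[[p]]$transitive)) {
      repeat {
        changed <- FALSE
        for (e in acc) {
          f <- e$filler
          if (f$kind == "some" && identical(f$property, p)) {
            for (g in oracle_sup_structs(graph, f$filler)) {
              if (add(expr_some(p, g))) changed <- TRUE
            }
          }
        }
        if (!changed) break
      }
    }
    return(acc)
  }
  c(list(expr),
    unlist(lapply(expr$args, oracle_sup_structs, graph = graph),
           recursive = FALSE))
}

oracle_superclasses <- function(graph, expr) {
  # character vector of renderings (reflexive set)
  sort(unique(vapply(oracle_sup_structs(graph, expr), oracle_render,
                     character(1L))))
}

oracle_subsumer_keys <- function(eq, graph) {
  se <- oracle_superclasses(graph, eq$entity)
  sq <- oracle_superclasses(graph, eq$quality)
  sr <- if (!is.null(eq$related_entity)) {
    oracle_superclasses(graph, eq$related_entity)
  } else ""
  triples <- as.vector(outer(
    as.vector(outer(se, sq, function(a, b) paste0("T:", a, "\x1f", b))),
    sr, function(ab, c) paste0(ab, "\x1f", c)))
  conj <- c(oracle_render(eq$quality),
            paste0("(inheres_in some ", oracle_render(eq$entity), ")"),
            if (!is.null(eq$related_entity)) {
              paste0("(towards some ", oracle_render(eq$related_entity), ")")
            })
  self <- paste0("(", paste(sort(conj, method = "radix"), collapse = " and "),
                 ")")
  xs <- unique(c(self, sq,
                 paste0("(inheres_in some ", se, ")"),
                 if (!is.null(eq$related_entity)) {
                   paste0("(towards some ", sr, ")")
                 }))
  sort(unique(c(triples, paste0("X:", xs))))
}

oracle_jaccard <- function(eq1, eq2, graph) {
  s1 <- oracle_subsumer_keys(eq1, graph)
  s2 <- oracle_subsumer_keys(eq2, graph)
  length(intersect(s1, s2)) / length(union(s1, s2))
}

oracle_pp_pr <- function(ref_eqs, test_eqs, graph) {
  best_for_test <- numeric(length(test_eqs))
  for (j in seq_along(test_eqs)) {
    vals <- numeric(length(ref_eqs))
    for (i in seq_along(ref_eqs)) {
      vals[i] <- oracle_jaccard(ref_eqs[[i]], test_eqs[[j]], graph)
    }
    best_for_test[j] <- max(vals)
  }
  best_for_ref <- numeric(length(ref_eqs))
  for (i in seq_along(ref_eqs)) {
    vals <- numeric(length(test_eqs))
    for (j in seq_along(test_eqs)) {
      vals[j] <- oracle_jaccard(ref_eqs[[i]], test_eqs[[j]], graph)
    }
    best_for_ref[i] <- max(vals)
  }
  list(PP = sum(best_for_test) / length(test_eqs),
       PR = sum(best_for_ref) / length(ref_eqs))
}

# does annotation a subsume annotation b? (componentwise, via the oracle
# ancestor closure; named/composite components handled alike)
oracle_eq_subsumes <- function(graph, a, b) {
  if (is.null(a$related_entity) != is.null(b$related_entity)) return(FALSE)
  sup_of <- function(x) oracle_superclasses(graph, x)
  ok <- oracle_render(a$entity) %in% sup_of(b$entity) &&
    oracle_render(a$quality) %in% sup_of(b$quality)
  if (!ok) return(FALSE)
  is.null(a$related_entity) ||
    oracle_render(a$related_entity) %in% sup_of(b$related_entity)
}

oracle_in <- function(eq, corpus, graph) {
  f <- 0
  for (key in names(corpus$eqs)) {
    if (oracle_eq_subsumes(graph, eq, corpus$eqs[[key]])) {
      f <- f + corpus$counts[[key]]
    }
  }
  if (f == 0) return(1)
  p <- f / corpus$total
  if (p == 1) 0 else -log(p) / log(corpus$total)
}

# random complete EQ over a generated graph; optionally post-composed E
oracle_random_eq <- function(graph, recompose = FALSE) {
  labs <- vapply(graph$classes, function(cl) cl$label, character(1L))
  anat <- names(labs)[grepl("anatomical structure$", labs)]
  qual <- names(labs)[grepl(" quality$", labs)]
  ids <- names(graph$classes)
  in_branch <- function(root) {
    ids[vapply(ids, function(t) root %in% oracle_ancestors(graph, t),
               logical(1L))]
  }
  e_pool <- setdiff(in_branch(anat), anat)
  q_pool <- setdiff(in_branch(qual), qual)
  e <- expr_named(sample(e_pool, 1L))
  if (recompose) {
    p1 <- sample(graph$isa_parents[[e$term]], 1L)
    e <- expr_and(expr_named(p1),
                  expr_some("part_of", expr_named(sample(e_pool, 1L))))
  }
  eq_annotation(e, expr_named(sample(q_pool, 1L)))
}
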