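
# Run code under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-state substream seed: fanning one master seed out per state keeps
# earlier states identical when more states are requested.
substream_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647
}

syn_id <- function(prefix, i) sprintf("%s:%07d", prefix, i)

#' Generate a seeded random ontology
#'
#' Builds a rooted acyclic `is_a` graph in which every class is
#' reachable from the root.  The root has two top-level branches,
#' an anatomical-structure branch (entity terms) and a quality branch
#' (quality terms), mirroring the anatomy/quality split of real EQ
#' vocabularies; remaining classes are assigned alternately to the two
#' branches, each with 1 to `max_parents` parents drawn from its
#' branch.  A transitive `part_of` property is declared and a small
#' fraction of anatomy classes receive a `part_of` relationship edge;
#' `inheres_in` and `towards` are declared for post-composition.
#' Deterministic for a given seed.
#'
#' @param n_classes Total number of classes (>= 1).
#' @param max_parents Maximum `is_a` parents per class.
#' @param seed Integer seed.
#' @param p_partof Fraction of anatomy classes given a `part_of` edge.
#' @param prefix Term-id prefix.
#' @return An `eqsim_graph`.
#' @export
gen_ontology <- function(n_classes, max_parents = 2L, seed = 1L,
                         p_partof = 0.15, prefix = "SYN") {
  stopifnot(n_classes >= 1L, max_parents >= 1L)
  with_seed(seed, {
    ids <- vapply(seq_len(n_classes), function(i) syn_id(prefix, i),
                  character(1L))
    classes <- list()
    isa <- list()
    branch <- character(n_classes)   # "", "anat", "qual"
    classes[[ids[[1L]]]] <- list(label = paste0(prefix, " root"),
                                 synonyms = character(0), obsolete = FALSE)
    branch[[1L]] <- "root"
    if (n_classes >= 2L) {
      classes[[ids[[2L]]]] <- list(label = paste0(prefix, " anatomical structure"),
                                   synonyms = character(0), obsolete = FALSE)
      isa[[ids[[2L]]]] <- ids[[1L]]
      branch[[2L]] <- "anat"
    }
    if (n_classes >= 3L) {
      classes[[ids[[3L]]]] <- list(label = paste0(prefix, " quality"),
                                   synonyms = character(0), obsolete = FALSE)
      isa[[ids[[3L]]]] <- ids[[1L]]
      branch[[3L]] <- "qual"
    }
    for (i in seq_len(n_classes)[-seq_len(min(3L, n_classes))]) {
      b <- if (i %% 2L == 0L) "anat" else "qual"
      pool <- which(branch == b & seq_len(n_classes) < i)
      k <- sample.int(max_parents, 1L)
      parents <- ids[sample(pool, min(k, length(pool)))]
      classes[[ids[[i]]]] <- list(label = paste0(prefix, " class ", i),
                                  synonyms = character(0), obsolete = FALSE)
      isa[[ids[[i]]]] <- parents
      branch[[i]] <- b
    }
    anat <- which(branch == "anat")
    rel <- data.frame(subject = character(0), property = character(0),
                      object = character(0), stringsAsFactors = FALSE)
    if (length(anat) >= 3L) {
      cand <- anat[-1L]            # branch root keeps no part_of edge
      chosen <- cand[stats::runif(length(cand)) < p_partof]
      for (i in chosen) {
        target <- sample(setdiff(anat, i), 1L)
        rel <- rbind(rel, data.frame(subject = ids[[i]], property = "part_of",
                                     object = ids[[target]],
                                     stringsAsFactors = FALSE))
      }
    }
    ontology_graph(classes, isa, rel,
                   list(part_of = list(transitive = TRUE),
                        inheres_in = list(transitive = FALSE),
                        towards = list(transitive = FALSE)))
  })
}

DIVERGENCE_MODES <- c("exact", "subsumption", "sibling", "unrelated",
                      "recompose", "missing", "incomplete")

#' Divergence profile for paired synthetic annotation sources
#'
#' Assigns each character state one mode of curator disagreement:
#' `exact` (same annotation), `subsumption` (a component replaced by an
#' ancestor — "different but related" term choice), `sibling` (a
#' sister term), `unrelated` (a term from a disjoint region),
#' `recompose` (the same meaning re-expressed as a `part_of`
#' post-composition), `missing` (an annotation dropped) and
#' `incomplete` (an unresolvable term emitted).  Probabilities must be
#' in `[0, 1]` and sum to at most 1; unassigned mass goes to `exact`.
#'
#' @param p_exact Probability of exact agreement, or `NULL` to take
#'   the remainder.
#' @param p_subsumption,p_sibling,p_unrelated,p_recompose,p_missing,p_incomplete
#'   Mode probabilities.
#' @return An object of class `eqsim_profile` (named probability
#'   vector over the seven modes).
#' @export
divergence_profile <- function(p_exact = NULL, p_subsumption = 0,
                               p_sibling = 0, p_unrelated = 0,
                               p_recompose = 0, p_missing = 0,
                               p_incomplete = 0) {
  others <- c(subsumption = p_subsumption, sibling = p_sibling,
              unrelated = p_unrelated, recompose = p_recompose,
              missing = p_missing, incomplete = p_incomplete)
  if (any(others < 0 | others > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(p_exact)) {
    if (p_exact < 0 || p_exact > 1) stop("probabilities must lie in [0, 1]")
    if (p_exact + sum(others) > 1 + 1e-9) {
      stop("mode probabilities must sum to at most 1")
    }
  }
  p_exact <- 1 - sum(others)     # remainder -> exact
  p <- c(exact = p_exact, others)
  if (any(p < -1e-9)) stop("mode probabilities must sum to at most 1")
  p <- pmax(p, 0)
  structure(p / sum(p), class = "eqsim_profile")
}

#' Illustrative default divergence profile
#'
#' Mode frequencies are free parameters of the generator, not
#' estimates of any particular curation team; the default exact-match
#' mass of 0.26 is of the order observed in published inter-curator
#' comparisons, with the remainder spread over the related-term modes.
#'
#' @return An `eqsim_profile`.
#' @export
default_profile <- function() {
  divergence_profile(p_exact = 0.26, p_subsumption = 0.30, p_sibling = 0.18,
                     p_unrelated = 0.06, p_recompose = 0.10,
                     p_missing = 0.05, p_incomplete = 0.05)
}

graph_components <- function(graph) {
  # weak components of the is_a graph, labeled by smallest member id
  ids <- names(graph$classes)
  comp <- stats::setNames(ids, ids)
  find <- function(x) {
    while (comp[[x]] != x) x <- comp[[x]]
    x
  }
  for (ch in names(graph$isa_parents)) {
    for (p in graph$isa_parents[[ch]]) {
      a <- find(ch); b <- find(p)
      if (a != b) comp[[max(a, b)]] <- min(a, b)
    }
  }
  vapply(ids, find, character(1L))
}

#' Generate a pair of annotation sources with controlled divergence
#'
#' Produces a reference source with 1–3 complete EQ annotations per
#' character state (entities from the anatomy branch, qualities from
#' the quality branch of the first graph component) and a test source
#' derived from it state by state according to a [divergence_profile()];
#' the mode drawn for each state is returned as its truth label.  In
#' `unrelated` mode replacement terms come from a different graph
#' component when the graph has one (giving no shared subsumers at
#' all), else from the opposite branch.  One master seed fans out to
#' per-state substreams, so earlier states are unchanged when
#' `n_states` grows.
#'
#' @param graph An `eqsim_graph` with at least 5 classes.
#' @param n_states Number of character states.
#' @param profile An `eqsim_profile`.
#' @param seed Integer master seed.
#' @param study Study label for the state keys.
#' @return A list with `ref` and `test` (`eqsim_source`) and `truth`
#'   (data frame `study`, `character_id`, `state_id`, `mode`).
#' @export
gen_source_pair <- function(graph, n_states, profile = default_profile(),
                            seed = 1L, study = "S1") {
  stopifnot(inherits(graph, "eqsim_graph"), n_states >= 1L)
  if (!inherits(profile, "eqsim_profile")) stop("profile must be an eqsim_profile")
  live <- names(graph$classes)[!vapply(graph$classes, function(cl)
    isTRUE(cl$obsolete), logical(1L))]
  if (length(live) < 5L) stop("graph needs at least 5 non-obsolete classes")
  comp <- graph_components(graph)
  home <- comp[[sort(live)[[1L]]]]
  home_terms <- live[comp[live] == home]
  away_terms <- live[comp[live] != home]

  labs <- vapply(graph$classes[home_terms], function(cl)
    cl$label %||% "", character(1L))
  anat_root <- home_terms[grepl("anatomical structure$", labs)]
  qual_root <- home_terms[grepl(" quality$", labs)]
  in_branch <- function(root) {
    home_terms[vapply(home_terms, function(t)
      root %in% term_ancestors(graph, t), logical(1L))]
  }
  if (length(anat_root) == 1L && length(qual_root) == 1L) {
    e_pool <- setdiff(in_branch(anat_root), anat_root)
    q_pool <- setdiff(in_branch(qual_root), qual_root)
    if (!length(e_pool)) e_pool <- anat_root
    if (!length(q_pool)) q_pool <- qual_root
  } else {
    e_pool <- q_pool <- home_terms
  }

  named_eq <- function(e, q) eq_annotation(expr_named(e), expr_named(q))

  diverge_eq <- function(eq, mode) {
    e <- eq$entity$term; q <- eq$quality$term
    switch(mode,
      exact = eq,
      subsumption = {
        # a direct parent: the gentlest "related but more general" choice,
        # keeping this mode above sibling replacement on average
        anc <- graph$isa_parents[[e]]
        if (length(anc)) named_eq(sample(anc, 1L), q)
        else {
          anc_q <- graph$isa_parents[[q]]
          if (length(anc_q)) named_eq(e, sample(anc_q, 1L)) else eq
        }
      },
      sibling = {
        parents <- graph$isa_parents[[e]]
        sibs <- character(0)
        for (p in parents) {
          kids <- names(graph$isa_parents)[vapply(graph$isa_parents,
            function(ps) p %in% ps, logical(1L))]
          sibs <- union(sibs, setdiff(kids, e))
        }
        sibs <- intersect(sibs, e_pool)
        if (length(sibs)) named_eq(sample(sibs, 1L), q)
        else diverge_eq(eq, "subsumption")
      },
      unrelated = {
        pool <- if (length(away_terms) >= 2L) away_terms
                else setdiff(home_terms, c(e_pool, q_pool))
        if (length(pool) < 2L) pool <- home_terms
        picks <- sample(pool, 2L)
        named_eq(picks[[1L]], picks[[2L]])
      },
      recompose = {
        parents <- graph$isa_parents[[e]]
        if (!length(parents)) return(eq)
        p1 <- sample(parents, 1L)
        gp <- graph$isa_parents[[p1]]
        anchor <- if (length(gp)) sample(gp, 1L) else p1
        eq_annotation(expr_and(expr_named(p1),
                               expr_some("part_of", expr_named(anchor))),
                      expr_named(q))
      },
      incomplete = eq_annotation("MISSING:0000001", expr_named(q),
                                 graph = graph),
      stop("unhandled mode ", mode))
  }

  ref_states <- list(); test_states <- list(); truth <- list()
  modes <- names(profile)
  for (k in seq_len(n_states)) {
    with_seed(substream_seed(seed, k), {
      mode <- sample(modes, 1L, prob = as.numeric(profile))
      n_eq <- sample.int(3L, 1L)
      refs <- lapply(seq_len(n_eq), function(.)
        named_eq(sample(e_pool, 1L), sample(q_pool, 1L)))
      tests <- switch(mode,
        missing = lapply(refs[-length(refs)], identity),
        incomplete = c(lapply(refs[-1L], identity),
                       list(diverge_eq(refs[[1L]], "incomplete"))),
        lapply(refs, diverge_eq, mode = mode))
      cid <- sprintf("c%04d", k)
      ref_states[[k]] <- character_state(study, cid, "s1",
        character_text = paste("synthetic character", k),
        state_text = "state 1", annotations = refs)
      test_states[[k]] <- character_state(study, cid, "s1",
        character_text = paste("synthetic character", k),
        state_text = "state 1", annotations = tests)
      truth[[k]] <- data.frame(study = study, character_id = cid,
                                state_id = "s1", mode = mode,
                                stringsAsFactors = FALSE)
    })
  }
  list(ref = annotation_source("REF", ref_states),
       test = annotation_source("TEST", test_states),
       truth = do.call(rbind, truth))
}
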