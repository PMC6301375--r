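test_that("generated ontologies are rooted DAGs, deterministic per seed", {
  g1 <- gen_ontology(1, seed = 1)
  expect_equal(length(g1$classes), 1L)
  g <- gen_ontology(50, max_parents = 2, seed = 42)
  g_again <- gen_ontology(50, max_parents = 2, seed = 42)
  expect_identical(g$isa_parents, g_again$isa_parents)
  expect_identical(g$rel_edges, g_again$rel_edges)
  expect_false(identical(g$isa_parents,
                         gen_ontology(50, max_parents = 2, seed = 43)$isa_parents))
  # acyclic by construction (the constructor runs a topological sort),
  # and every class reaches the root
  root <- "SYN:0000001"
  for (t in names(g$classes)) {
    expect_true(root %in% term_ancestors(g, t))
  }
  expect_error(gen_ontology(0), "n_classes")
})

test_that("profiles validate and route remainder mass to exact", {
  p <- divergence_profile(p_subsumption = 0.3, p_sibling = 0.2)
  expect_equal(unname(p["exact"]), 0.5)
  expect_equal(sum(p), 1)
  expect_error(divergence_profile(p_subsumption = 1.4), "\\[0, 1\\]")
  expect_error(divergence_profile(p_exact = 0.5, p_subsumption = 0.7),
               "sum")
  expect_equal(sum(default_profile()), 1)
})

test_that("source pairs are deterministic and stable under state growth", {
  g <- gen_ontology(40, seed = 3)
  p1 <- gen_source_pair(g, 20, default_profile(), seed = 3)
  p2 <- gen_source_pair(g, 20, default_profile(), seed = 3)
  expect_identical(lapply(p1$ref$states, function(s)
    vapply(s$annotations, eq_render, character(1))),
    lapply(p2$ref$states, function(s)
      vapply(s$annotations, eq_render, character(1))))
  # per-state substreams: the first 20 states survive growing to 30
  p3 <- gen_source_pair(g, 30, default_profile(), seed = 3)
  expect_identical(p3$truth$mode[1:20], p1$truth$mode)
  expect_identical(names(p1$ref$states),
                   names(p3$ref$states)[seq_len(20)])
})

test_that("all-exact pairs are identical; set metrics score 1", {
  g <- gen_ontology(40, seed = 11)
  pair <- gen_source_pair(g, 30, divergence_profile(p_exact = 1), seed = 11)
  cmp <- source_similarity(pair$ref, pair$test, c("PP", "PR", "JSIM"), g)
  expect_true(all(cmp$summary$mean == 1))
  expect_true(all(pair$truth$mode == "exact"))
})

test_that("all-unrelated pairs across disjoint components score 0", {
  g <- merge_ontologies(list(gen_ontology(20, seed = 1, prefix = "AA"),
                             gen_ontology(20, seed = 2, prefix = "BB")))
  pair <- gen_source_pair(g, 25, divergence_profile(p_unrelated = 1),
                          seed = 5)
  cmp <- source_similarity(pair$ref, pair$test, "JSIM", g)
  expect_equal(cmp$summary$mean, 0)
})

test_that("incomplete-mode states score 0 on every metric", {
  g <- gen_ontology(40, seed = 19)
  pair <- gen_source_pair(g, 30, divergence_profile(p_exact = 0.5,
                                                    p_incomplete = 0.5),
                          seed = 19)
  inc_states <- pair$truth$character_id[pair$truth$mode == "incomplete"]
  expect_gt(length(inc_states), 0)
  cmp <- source_similarity(pair$ref, pair$test, graph = g)
  ps <- cmp$per_state
  for (cid in inc_states) {
    rows <- ps[ps$character_id == cid, ]
    expect_true(all(rows$value == 0))
    expect_true(all(rows$zeroed))
  }
})

test_that("exact-match fraction recovers the profile probability", {
  g <- gen_ontology(40, seed = 29)
  profile <- divergence_profile(p_exact = 0.5, p_subsumption = 0.5)
  pair <- gen_source_pair(g, 400, profile, seed = 29)
  cmp <- source_similarity(pair$ref, pair$test, "JSIM", g)
  frac <- mean(cmp$per_state$value == 1)
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(frac - 0.5), 3 * se)
  # truth labels agree with the observed outcome
  exact_truth <- pair$truth$mode == "exact"
  expect_equal(cmp$per_state$value[exact_truth] == 1,
               rep(TRUE, sum(exact_truth)))
})

test_that("mean similarity decreases along the divergence ordering", {
  modes <- c("exact", "subsumption", "sibling", "unrelated")
  mk_profile <- function(mode) {
    switch(mode,
           exact = divergence_profile(p_exact = 1),
           subsumption = divergence_profile(p_subsumption = 1),
           sibling = divergence_profile(p_sibling = 1),
           unrelated = divergence_profile(p_unrelated = 1))
  }
  means <- matrix(NA_real_, nrow = 8, ncol = length(modes),
                  dimnames = list(NULL, modes))
  for (s in 1:8) {
    g <- gen_ontology(40, seed = 100 + s)
    for (m in modes) {
      pair <- gen_source_pair(g, 40, mk_profile(m), seed = 200 + s)
      means[s, m] <- source_similarity(pair$ref, pair$test, "JSIM",
                                       g)$summary$mean
    }
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) < 0))
  # rank ordering holds seed by seed for the extremes
  expect_true(all(means[, "exact"] > means[, "unrelated"]))
})

test_that("recompose mode keeps semantic overlap above unrelated", {
  for (s in 1:5) {
    g <- gen_ontology(40, seed = 300 + s)
    rec <- gen_source_pair(g, 30, divergence_profile(p_recompose = 1),
                           seed = s)
    unr <- gen_source_pair(g, 30, divergence_profile(p_unrelated = 1),
                           seed = s)
    m_rec <- source_similarity(rec$ref, rec$test, "JSIM", g)$summary$mean
    m_unr <- source_similarity(unr$ref, unr$test, "JSIM", g)$summary$mean
    expect_gt(m_rec, m_unr)
  }
})
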