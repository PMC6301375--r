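test_that("Jaccard: identity 1, disjoint 0, toy pair 11/21", {
  g <- toy_graph()
  a <- toy_eq("U:3", "P:3")
  b <- toy_eq("U:4", "P:3")
  expect_equal(jaccard(a, a, g), 1)
  # hand enumeration: shared triples 2x3, shared expr supers 3 Q + 2
  # inheres_in; union 12 triples + 9 expr supers
  expect_equal(jaccard(a, b, g), 11 / 21)
  expect_gt(jaccard(a, b, g), 0.5)
  expect_lt(jaccard(a, b, g), 0.65)
  # disjoint rooted components share nothing
  g2 <- merge_ontologies(list(gen_ontology(12, seed = 1, prefix = "AA"),
                              gen_ontology(12, seed = 2, prefix = "BB")))
  eq_a <- eq_annotation(expr_named("AA:0000004"), expr_named("AA:0000005"))
  eq_b <- eq_annotation(expr_named("BB:0000004"), expr_named("BB:0000005"))
  expect_equal(jaccard(eq_a, eq_b, g2), 0)
  expect_error(jaccard(eq_annotation(expr_named("U:3")), a, g), "incomplete")
})

test_that("Jaccard is symmetric, reflexive and bounded on random pairs", {
  set.seed(5)
  for (seed in 1:5) {
    g <- gen_ontology(30, seed = seed)
    for (i in 1:8) {
      a <- oracle_random_eq(g, recompose = i %% 3 == 0)
      b <- oracle_random_eq(g)
      j1 <- jaccard(a, b, g)
      expect_equal(j1, jaccard(b, a, g))
      expect_gte(j1, 0); expect_lte(j1, 1)
      expect_equal(jaccard(a, a, g), 1)
    }
  }
})

test_that("corpus counting is additive across sources", {
  a <- toy_eq("U:3", "P:3")
  b <- toy_eq("U:4", "P:4")
  s1 <- toy_source("C1", a)
  expect_equal(build_corpus(list(s1))$total, 1L)
  s2 <- toy_source("C2", a)
  s3 <- toy_source("C3", a, b)
  corp <- build_corpus(list(s1, s2, s3))
  expect_equal(corp$total, 4L)
  expect_equal(unname(corp$counts[eq_render(a)]), 3L)
  # incomplete annotations never enter the corpus
  s4 <- toy_source("C4", eq_annotation("XX:1", expr_named("P:3"),
                                       graph = toy_graph()))
  corp2 <- build_corpus(list(s1, s4))
  expect_equal(corp2$total, 1L)
  expect_equal(corp2$n_incomplete, 1L)
})

test_that("information content follows the annotation-frequency formulas", {
  g <- toy_graph()
  b <- toy_eq("U:3", "P:3")   # 'B': three annotations
  c_ <- toy_eq("U:4", "P:3")  # 'C': one annotation
  corp <- build_corpus(list(toy_source("A", b, b, b, c_)))
  icb <- information_content(b, corp, g)
  expect_equal(icb$I, log(4 / 3))
  expect_equal(icb$In, log(4 / 3) / log(4))
  # frequency-1 node attains the maximum
  expect_equal(information_content(c_, corp, g)$In, 1)
  expect_equal(information_content(c_, corp, g)$I, log(4))
  # a node subsuming every annotation has I = 0 (here: the shared parent
  # triple subsumes both leaves)
  parent_node <- list(e = expr_named("U:2"), q = expr_named("P:3"), re = NULL)
  ic_root <- information_content(parent_node, corp, g)
  expect_equal(ic_root$I, 0)
  expect_equal(ic_root$In, 0)
  # node subsuming nothing annotated: bounded maximum, with a note
  stray <- list(e = expr_named("U:1"), q = expr_named("P:4"), re = NULL)
  expect_message(ic0 <- information_content(stray, corp, g), "Imax")
  expect_equal(ic0$In, 1)
})

test_that("IC is anti-monotone along subsumption", {
  g <- gen_ontology(30, seed = 41)
  pair <- gen_source_pair(g, 40, divergence_profile(p_subsumption = 0.5),
                          seed = 41)
  corp <- build_corpus(list(pair$ref, pair$test))
  set.seed(41)
  for (key in sample(names(corp$eqs), 10)) {
    eq <- corp$eqs[[key]]
    anc_e <- term_ancestors(g, eq$entity$term)
    general <- eq_annotation(expr_named(anc_e[[1]]), eq$quality)
    ic_g <- suppressMessages(information_content(general, corp, g))
    ic_s <- suppressMessages(information_content(eq, corp, g))
    ok <- render_expr(general$entity) %in%
      vapply(superclasses(g, eq$entity), render_expr, character(1))
    if (ok) expect_lte(ic_g$I, ic_s$I + 1e-12)
    expect_gte(ic_s$In, 0); expect_lte(ic_s$In, 1)
  }
})

test_that("LCS similarity: self-identity, parent triple, empty overlap", {
  g <- toy_graph()
  a <- toy_eq("U:3", "P:3")
  b <- toy_eq("U:4", "P:3")
  other <- toy_eq("U:2", "P:4")
  corp <- build_corpus(list(toy_source("A", a, b, other, other)))
  # LCS of a node with itself is the node
  expect_equal(lcs_similarity(a, a, corp, g),
               suppressMessages(information_content(a, corp, g))$In)
  # siblings: only informative common subsumer is the parent triple
  # (U:2, P:3), which subsumes a and b but not 'other': p = 2/4
  expect_equal(lcs_similarity(a, b, corp, g), log(2) / log(4))
  # disjoint components: no common subsumer
  g2 <- merge_ontologies(list(gen_ontology(12, seed = 1, prefix = "AA"),
                              gen_ontology(12, seed = 2, prefix = "BB")))
  eq_a <- eq_annotation(expr_named("AA:0000004"), expr_named("AA:0000005"))
  eq_b <- eq_annotation(expr_named("BB:0000004"), expr_named("BB:0000005"))
  corp2 <- build_corpus(list(toy_source("A", eq_a), toy_source("B", eq_b)))
  expect_equal(lcs_similarity(eq_a, eq_b, corp2, g2), 0)
})

test_that("lcs_similarity(x, x) equals In(x) on generated corpora", {
  g <- gen_ontology(25, seed = 55)
  pair <- gen_source_pair(g, 30, divergence_profile(p_subsumption = 0.4,
                                                    p_sibling = 0.3),
                          seed = 55)
  corp <- build_corpus(list(pair$ref, pair$test))
  set.seed(55)
  for (key in sample(names(corp$eqs), 12)) {
    eq <- corp$eqs[[key]]
    expect_equal(lcs_similarity(eq, eq, corp, g),
                 suppressMessages(information_content(eq, corp, g))$In)
  }
})

test_that("partial precision/recall implement best-match averaging", {
  g <- toy_graph()
  a <- toy_eq("U:3", "P:3")
  b <- toy_eq("U:4", "P:3")
  jstar <- jaccard(a, b, g)
  expect_equal(partial_scores(list(a), list(a), g), list(PP = 1, PR = 1))
  # extra dissimilar test annotation dilutes PP, not PR
  ps <- partial_scores(list(a), list(a, b), g)
  expect_equal(ps$PR, 1)
  expect_equal(ps$PP, (1 + jstar) / 2)
  # mirror case
  ps2 <- partial_scores(list(a, b), list(a), g)
  expect_equal(ps2$PP, 1)
  expect_equal(ps2$PR, (1 + jstar) / 2)
  expect_error(partial_scores(list(), list(a), g), "non-empty")
})

test_that("PP/PR duality and monotonicity under added annotations", {
  g <- gen_ontology(30, seed = 61)
  set.seed(61)
  for (i in 1:15) {
    refs <- lapply(seq_len(sample(1:3, 1)), function(.) oracle_random_eq(g))
    tests <- lapply(seq_len(sample(1:3, 1)), function(.) oracle_random_eq(g))
    f <- partial_scores(refs, tests, g)
    r <- partial_scores(tests, refs, g)
    expect_equal(f$PP, r$PR)
    expect_equal(f$PR, r$PP)
    # PR never decreases when the test list grows
    extra <- oracle_random_eq(g)
    f2 <- partial_scores(refs, c(tests, list(extra)), g)
    expect_gte(f2$PR, f$PR - 1e-12)
  }
})

test_that("state similarity takes best matches and applies the zero rule", {
  g <- toy_graph()
  a <- toy_eq("U:3", "P:3"); b <- toy_eq("U:4", "P:3")
  c_ <- toy_eq("U:2", "P:4")
  st <- function(...) character_state("S", "c1", "s1",
                                      annotations = list(...))
  same <- state_similarity(st(a), st(a), "JSIM", g)
  expect_equal(same$value, 1)
  expect_false(same$zeroed)
  # 3x2 annotations: the max of the six pairwise scores
  r3 <- st(a, b, c_); t2 <- st(b, c_)
  jmax <- max(vapply(list(a, b, c_), function(x)
    max(jaccard(x, b, g), jaccard(x, c_, g)), numeric(1)))
  expect_equal(state_similarity(r3, t2, "JSIM", g)$value, jmax)
  # incomplete annotation on either side zeroes the state
  inc <- eq_annotation("XX:1", expr_named("P:3"), graph = g)
  for (m in c("PP", "PR", "JSIM", "IN")) {
    z <- state_similarity(st(a), st(a, inc), m, g,
                          build_corpus(list(toy_source("A", a))))
    expect_equal(z$value, 0)
    expect_true(z$zeroed)
  }
  # empty state zeroes too
  z2 <- state_similarity(st(a), st(), "JSIM", g)
  expect_equal(z2$value, 0)
  expect_true(z2$zeroed)
  expect_error(state_similarity(st(a), character_state("S", "c2", "s1"),
                                "JSIM", g),
               "keys differ")
})

test_that("source similarity averages shared states and reports extras", {
  g <- toy_graph()
  a <- toy_eq("U:3", "P:3"); b <- toy_eq("U:4", "P:4")
  mk <- function(id, states) annotation_source(id, states)
  s_ref <- mk("R", list(
    character_state("S", "c1", "s1", annotations = list(a)),
    character_state("S", "c2", "s1", annotations = list(a)),
    character_state("S", "c3", "s1", annotations = list(a))))
  s_test <- mk("T", list(
    character_state("S", "c1", "s1", annotations = list(a)),
    character_state("S", "c2", "s1", annotations = list()),
    character_state("S", "c9", "s1", annotations = list(b))))
  cmp <- source_similarity(s_ref, s_test, "JSIM", g)
  # two shared states scoring 1 and 0
  expect_equal(cmp$summary$mean, 0.5)
  expect_equal(cmp$summary$n_states, 2L)
  expect_equal(attr(cmp, "n_only_ref"), 1L)
  expect_equal(attr(cmp, "n_only_test"), 1L)
  # excluding empty states drops the zero from the mean
  cmp2 <- source_similarity(s_ref, s_test, "JSIM", g,
                            empty_policy = "exclude")
  expect_equal(cmp2$summary$mean, 1)
  expect_equal(cmp2$summary$n_states, 1L)
  expect_error(source_similarity(s_ref, mk("X", list(
    character_state("Z", "c1", "s1"))), "JSIM", g), "share no")
})

test_that("a source compared with itself scores 1 on the set metrics", {
  g <- gen_ontology(40, seed = 71)
  pair <- gen_source_pair(g, 20, divergence_profile(p_exact = 1), seed = 71)
  cmp <- source_similarity(pair$ref, pair$ref, c("PP", "PR", "JSIM"), g)
  expect_true(all(cmp$summary$mean == 1))
  # IN of an identical pair equals the node's own normalized IC: 1 only
  # for frequency-1 nodes, so the mean sits in (0, 1]
  cmp_in <- source_similarity(pair$ref, pair$ref, "IN", g,
                              corpus = build_corpus(list(pair$ref)))
  expect_true(all(cmp_in$per_state$value > 0))
  expect_true(all(cmp_in$per_state$value <= 1))
})

test_that("all four metrics match the naive brute-force on random states", {
  set.seed(77)
  for (rep in 1:6) {
    g <- gen_ontology(sample(15:35, 1), seed = rep + 100)
    refs <- lapply(seq_len(sample(1:3, 1)), function(.)
      oracle_random_eq(g, recompose = rep %% 3 == 0))
    tests <- lapply(seq_len(sample(1:3, 1)), function(.) oracle_random_eq(g))
    ps <- partial_scores(refs, tests, g)
    or <- oracle_pp_pr(refs, tests, g)
    expect_equal(ps$PP, or$PP, tolerance = 1e-12)
    expect_equal(ps$PR, or$PR, tolerance = 1e-12)
    for (a in refs) for (b in tests) {
      expect_equal(jaccard(a, b, g), oracle_jaccard(a, b, g),
                   tolerance = 1e-12)
    }
    corp <- build_corpus(list(toy_source("R", refs[[1]]),
                              do.call(toy_source, c(list("T"), tests))))
    for (a in refs) {
      expect_equal(suppressMessages(information_content(a, corp, g))$In,
                   oracle_in(a, corp, g), tolerance = 1e-12)
    }
  }
})
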