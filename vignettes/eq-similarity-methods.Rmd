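---
title: "Measuring agreement between EQ phenotype annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agreement between EQ phenotype annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqsim)
```

## The problem

Evolutionary phenomics projects translate free-text character
descriptions from the systematics literature ("pectoral fin: absent")
into computable phenotypes using the entity–quality (EQ) formalism: an
anatomical Entity from an anatomy ontology bears a Quality from a
quality ontology, optionally relative to a Related Entity (e.g.
*nasal bone* — *in contact with* — *prefrontal bone*).  When no single
named term fits, curators build *post-compositions* on the fly, class
expressions such as `('gland' and (part_of some 'pelvis'))`.

Different curators — and text-mining software — routinely produce
different but semantically related annotations for the same character
state.  Counting only exact matches badly understates their agreement:
one curator's *dorsal fin* and another's *median fin* differ as
strings but are near neighbours in the ontology.  This package scores
agreement *semantically*, through the class structure of the
ontologies and the annotation density of the corpus, and provides the
rank statistics needed to analyze preference surveys over competing
annotation sources.

## From an annotation to its subsumer set

All four metrics operate on the *subsumer set* of an annotation: the
set of generalizations the ontologies license.  Materializing the full
`E x Q x RE` cross-product ontology up front would be prohibitively
large, so subsumers are generated per annotation:

1. The annotation is split into its components E, Q (and RE, when
   present), and also transformed into the combined class expression
   `Q and (inheres_in some E) [and (towards some RE)]`.
2. Superclasses of each component and of the combined expression are
   computed by structural rules on the merged ontology: `is_a`
   ancestors for named classes; `(p some F)` is subsumed by
   `(p some F')` for every superclass `F'` of `F`; an intersection is
   subsumed by each conjunct's superclasses and by itself; and nested
   restrictions over a transitive property (here `part_of`) collapse,
   `(part_of some (part_of some F))` into `(part_of some F')`.  This
   reproduces, for the expression shapes an EQ pipeline produces, what
   an EL reasoner derives over an ontology augmented with the
   `OP some U` existential vocabulary (`augment_with_existentials()`
   enumerates that vocabulary).  Named-class logical definitions are
   outside this fragment; subsuming quality terms do not carry
   definitions over anatomical entities, so this boundary does not
   change subsumer sets for these ontologies.  Sub-property reasoning
   (roles below `part_of`) is likewise not performed.
3. The component superclass sets `SE`, `SQ`, `SR` are combined into
   every `E–Q–RE` triple (`SE x SQ x SR`), and the combined
   expression's superclasses are added as a second family.

Two representation choices are deliberate and visible in results:

* **Subsumer sets are reflexive** — every annotation is a subsumer of
  itself.  This is what makes the Jaccard similarity of an annotation
  with itself exactly 1.
* **The two families stay distinguishable.**  A bare quality
  superclass counted inside a triple and the same class appearing as
  an expression superclass are distinct set elements, and triples with
  an RE never equal triples without one.  The union size used by the
  Jaccard metric therefore counts the two contributions separately; an
  undocumented deduplication would silently change every score.

For information-content purposes, however, the combined expression of
an annotation and its identity triple denote the *same node* of the ad
hoc EQ graph, and are identified there (see below).  Cross-annotation
subsumption flows through the triple family: annotation `N` subsumes
annotation `M` exactly when `N`'s identity triple appears among `M`'s
triples.

```{r}
g <- ontology_graph(
  classes = list(
    "U:1" = list(label = "anatomical structure", synonyms = character(0), obsolete = FALSE),
    "U:2" = list(label = "fin",           synonyms = character(0), obsolete = FALSE),
    "U:3" = list(label = "pectoral fin",  synonyms = character(0), obsolete = FALSE),
    "U:4" = list(label = "pelvic fin",    synonyms = character(0), obsolete = FALSE),
    "P:1" = list(label = "quality",       synonyms = character(0), obsolete = FALSE),
    "P:2" = list(label = "size",          synonyms = character(0), obsolete = FALSE),
    "P:3" = list(label = "increased size", synonyms = character(0), obsolete = FALSE)),
  isa_parents = list("U:2" = "U:1", "U:3" = "U:2", "U:4" = "U:2",
                     "P:2" = "P:1", "P:3" = "P:2"),
  properties = list(part_of = list(transitive = TRUE)))
eq <- eq_annotation(expr_named("U:3"), expr_named("P:3"))
subsumers(eq, g)
```

## The four metrics

**Jaccard similarity.**  For annotations with subsumer sets `S(N1)`,
`S(N2)`,
`Jsim = |S(N1) n S(N2)| / |S(N1) u S(N2)|`:
1 for identical annotations, 0 when nothing is shared, and graded
credit in between driven purely by graph structure.

**Normalized information content.**  Graph distance ignores how
*specific* a region of the ontology is in practice.  The information
content of a node is `I = -log p`, where `p` is the fraction of corpus
annotations falling on the node or anything it subsumes, and is
normalized by `Imax = -log(1/total)` to `In = I/Imax` in `[0, 1]`.
The similarity of two annotations is the `In` of their least common
subsumer (LCS): among common subsumers that do not strictly subsume
another common subsumer, the one with the highest `I` (ties broken
lexicographically on the canonical key so reports are deterministic).
Logs are natural; `In` is base-invariant.

Degenerate cases are bounded, not infinite: a node subsuming no
annotated node (`p = 0`) is assigned `In = 1` with a note, and `In`
is 0 when `p = 1`.  Because the combined-expression encoding of an
annotation is identified with its identity triple at the node level,
`lcs_similarity(x, x)` equals `In(x)` exactly — the self-similarity of
an annotation is its own specificity, which is 1 only for nodes
annotated exactly once in the corpus.  The corpus should contain every
annotation set under comparison (all curation rounds plus machine
output); `build_corpus()` excludes unresolvable annotations, which
have no node.

**Partial precision and recall.**  At the character-state level, with
`X` reference annotations and `Y` test annotations,
`PP = (1/Y) * sum_j max_i Jsim(ref_i, test_j)` and
`PR = (1/X) * sum_i max_j Jsim(ref_i, test_j)`.
PP drops when the test curator adds annotations dissimilar from
everything in the reference; PR drops when reference annotations have
no good counterpart.  The two are exact transposes:
`PP(R, T) = PR(T, R)`, a property the test suite checks on thousands
of generated state pairs.

**Aggregation.**  For `JSIM` and `IN` the state score is the best
match — the maximum over all reference-by-test annotation pairs (the
alternative of taking the LCS of the best-Jaccard pair is *not* used;
the maximum is taken per metric).  Source-level consistency is the
arithmetic mean over the character states both sources curated; states
present in only one source are reported but excluded from the mean.

**The zero rule.**  A state containing an *incomplete* annotation —
one whose entity or quality failed to resolve to any ontology class —
scores 0 on all four metrics, as does a shared state one source left
without annotations.  Unresolvable content carries no checkable
semantics, so it earns no credit; the `zeroed` flag in the per-state
report makes these states auditable.  The empty-state behaviour is a
policy (`empty_policy = "zero"` by default, `"exclude"` to keep such
states out of the mean), since one can argue either reading.

## Rank statistics for preference surveys

When authors rank competing annotation sources per character state,
two chi-square statistics summarize the survey.  Anderson's `A`
compares the full rank-count matrix `O(i, j)` against the uniform
expectation `n/t` and is referred to `(t-1)^2` degrees of freedom;
Friedman's `F` compares only the rank sums `R_i` and is referred to
`t-1` degrees of freedom, reaching its maximum `n(t-1)` at perfect
agreement.  The input contract demands full rankings (no ties) per
observation; respondents who skipped a character contribute no row,
so ragged surveys pool their complete rows (`rank_table()` reports how
many rows were dropped), and a midrank conversion is available — with
a warning — for data collected with ties.

Paired per-state score vectors from two conditions are compared with a
two-sided Wilcoxon signed-rank test.  Zero differences are common here
(many states agree exactly or are zeroed in both conditions), so the
convention matters: zeros participate in ranking and are then removed
(Pratt), the exact distribution is enumerated for up to 25 non-zero
differences — p-values near a family-wise threshold should not depend
on an approximation — and a continuity-corrected normal approximation
is used above that.  The comparison harness applies a Bonferroni
family-wise threshold of 0.0008 when requested.

## The synthetic-data generator

Real corpora of this kind are produced by slow expert curation, so the
package carries a seeded generator that emulates the documented modes
of curator divergence and makes every pipeline path testable.

`gen_ontology()` builds a rooted acyclic `is_a` graph with an anatomy
branch and a quality branch under one root, a transitive `part_of`
property, and a sprinkling (default 15%) of `part_of` edges among
anatomy classes.  `gen_source_pair()` writes a reference source with
1–3 complete annotations per state and derives a test source state by
state according to a `divergence_profile()`:

| mode | emulates |
|---|---|
| `exact` | same annotation chosen |
| `subsumption` | a direct parent chosen instead (related, more general) |
| `sibling` | a sister term chosen |
| `unrelated` | a term from a disjoint region (a second graph component, when present) |
| `recompose` | same meaning re-expressed as a `part_of` post-composition |
| `missing` | an annotation dropped |
| `incomplete` | an unresolvable term emitted |

The drawn mode is recorded per state as a truth label, so tests can
check parameter recovery: at `p_exact = 0.5` the fraction of states
scoring `Jsim = 1` lands within binomial error of 0.5, and mean
similarity falls monotonically along exact, subsumption, sibling,
unrelated.  The `subsumption` mode deliberately picks a *direct
parent* rather than an arbitrary ancestor: a remote ancestor can be
semantically farther than a sibling, which would scramble that
ordering.  Probabilities not assigned to a named mode default to
`exact`.  The `default_profile()` frequencies (0.26 exact, the rest
spread over the related-term modes) are illustrative — of the order
seen in published inter-curator comparisons, not an estimate of any
particular team.

One master seed fans out to one substream per state, so generating
more states never perturbs the earlier ones.

What the generator does *not* emulate: natural-language character
text, curator-specific term preferences, ontology gaps that force
provisional terms, and the long-tailed reuse of a few common qualities
(*absent*, *present*) in real data.  Passing tests on synthetic pairs
therefore demonstrate correctness of the arithmetic and the pipeline,
not calibration of the metrics on any real corpus.

## Numerical and design choices

* **Canonical renderings as identity.**  Intersections are flattened,
  deduplicated and sorted, so structurally equal expressions render
  identically; all set membership is by rendering.  Conjunct order in
  the input never changes a score.
* **Label resolution** is exact label first, then synonym, and an
  ambiguous or unknown label is an error with near-matches listed —
  silent guessing would corrupt annotations.
* **Obsolete classes** resolve for error reporting but are excluded
  from subsumption; merging keeps the first graph's label on conflict
  (with a warning) and unions synonym sets.
* **Incomplete annotations are retained**, with raw text, rather than
  dropped at parse time: the zero rule needs to see them.
* **Caching.**  Ancestor closures, expression superclasses and
  subsumer sets are memoized per graph; corpus membership sets per
  corpus.  Caches never cross a graph object, and a rebuilt graph
  starts cold, so determinism is unaffected.
* **Problem sizes.**  The bundled checks run on generated ontologies
  of 15–50 classes, source pairs of 40–400 states, and 200 random
  oracle instances — sizes at which an independent brute-force
  implementation (matrix-closure reachability, uncached enumeration)
  can confirm every score to 1e-12 while the whole suite stays quick.

## Limitations

* OBO flat files only (the `[Term]`/`[Typedef]` fragment); no OWL/XML.
* The structural fragment covers existential restrictions,
  intersections and one self-transitive property level — no property
  chains, sub-properties, equivalence axioms, negation or cardinality.
* Archived corpora distributed as NeXML need conversion to the TSV
  interchange format first.
* The metrics quantify agreement, not correctness: two curators can
  agree on a wrong annotation.
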