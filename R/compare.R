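write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Compare annotation sources pairwise and write report tables
#'
#' For every ordered pair of the given sources, computes the state-level
#' scores and the per-metric means (see [source_similarity()]) and
#' writes, under `out_dir`: one per-state TSV per pair
#' (`states_<REF>_vs_<TEST>.tsv`, rows sorted by state key) and a single
#' `summary.tsv` with one row per pair and metric carrying the mean, the
#' standard error and a two-standard-error bar.  With
#' `wilcoxon = TRUE`, per-metric paired Wilcoxon signed-rank tests
#' between every two comparisons that share a reference are written to
#' `wilcoxon.tsv`; `bonferroni` switches the significance threshold from
#' 0.05 to the family-wise 0.0008.
#'
#' Output is byte-identical across runs for identical inputs: state
#' keys, pairs and metrics are emitted in sorted order.
#'
#' @param sources Named list of `eqsim_source` (>= 2).
#' @param graph An `eqsim_graph`.
#' @param out_dir Output directory (created if needed).
#' @param metrics Metrics to compute.
#' @param corpus Corpus for `IN`; defaults to one built from all
#'   `sources`.
#' @param empty_policy Passed to [source_similarity()].
#' @param wilcoxon Whether to run the paired-test harness.
#' @param bonferroni Use the family-wise corrected threshold 0.0008.
#' @return Invisibly, a list with the `summary` data frame and the
#'   per-pair comparison objects.
#' @export
compare_sources <- function(sources, graph, out_dir,
                            metrics = EQ_METRICS, corpus = NULL,
                            empty_policy = "zero", wilcoxon = FALSE,
                            bonferroni = FALSE) {
  stopifnot(length(sources) >= 2L)
  ids <- vapply(sources, function(s) s$source_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate source ids")
  names(sources) <- ids
  ids <- sort(ids, method = "radix")
  if (is.null(corpus) && "IN" %in% metrics) corpus <- build_corpus(sources)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  comparisons <- list()
  summary_rows <- list()
  for (a in ids) for (b in ids) {
    if (a == b) next
    cmp <- source_similarity(sources[[a]], sources[[b]], metrics, graph,
                             corpus, empty_policy)
    pair <- paste0(a, "_vs_", b)
    comparisons[[pair]] <- cmp
    ps <- cmp$per_state
    ps$ref <- a; ps$test <- b
    write_tsv(ps[order(ps$study, ps$character_id, ps$state_id, ps$metric,
                       method = "radix"), ],
              file.path(out_dir, paste0("states_", pair, ".tsv")))
    s <- cmp$summary
    summary_rows[[pair]] <- data.frame(ref = a, test = b, s,
                                       err2se = 2 * s$sem,
                                       n_only_ref = attr(cmp, "n_only_ref"),
                                       n_only_test = attr(cmp, "n_only_test"),
                                       stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  summary <- summary[order(summary$ref, summary$test, summary$metric,
                           method = "radix"), ]
  write_tsv(summary, file.path(out_dir, "summary.tsv"))

  if (wilcoxon) {
    alpha <- if (bonferroni) 0.0008 else 0.05
    wrows <- list()
    pairs <- sort(names(comparisons), method = "radix")
    for (i in seq_along(pairs)) for (j in seq_along(pairs)) {
      if (i >= j) next
      p1 <- comparisons[[pairs[[i]]]]$per_state
      p2 <- comparisons[[pairs[[j]]]]$per_state
      for (m in sort(metrics)) {
        a1 <- p1[p1$metric == m, ]
        a2 <- p2[p2$metric == m, ]
        key1 <- paste(a1$study, a1$character_id, a1$state_id)
        key2 <- paste(a2$study, a2$character_id, a2$state_id)
        shared <- intersect(key1, key2)
        if (length(shared) < 2L) next
        pval <- paired_signed_rank(a1$value[match(shared, key1)],
                                   a2$value[match(shared, key2)])
        wrows[[length(wrows) + 1L]] <-
          data.frame(metric = m, comparison_1 = pairs[[i]],
                     comparison_2 = pairs[[j]], n = length(shared),
                     p = pval, alpha = alpha, significant = pval < alpha,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(wrows)) {
      write_tsv(do.call(rbind, wrows), file.path(out_dir, "wilcoxon.tsv"))
    }
  }
  invisible(list(summary = summary, comparisons = comparisons))
}

#' Summary statistics of an annotation corpus file
#'
#' Counts, for one annotation source: EQ phenotypes, characters,
#' character states, total and unique term usages per ontology
#' namespace (the term-id prefix), and the number of post-composed
#' expressions (slots that are not a bare named term).
#'
#' @param source An `eqsim_source`.
#' @return A list of counts: `n_phenotypes`, `n_characters`,
#'   `n_states`, `n_postcomposed`, `n_incomplete`, and `by_namespace`
#'   (data frame `namespace`, `total`, `unique`).
#' @export
corpus_stats <- function(source) {
  stopifnot(inherits(source, "eqsim_source"))
  n_phen <- 0L; n_post <- 0L; n_inc <- 0L
  usages <- character(0)
  chars <- character(0)
  for (st in source$states) {
    chars <- c(chars, paste(st$study, st$character_id, sep = "\r"))
    for (eq in st$annotations) {
      n_phen <- n_phen + 1L
      if (!eq$complete) n_inc <- n_inc + 1L
      for (slot in list(eq$entity, eq$quality, eq$related_entity)) {
        if (is.null(slot)) next
        if (slot$kind != "named") n_post <- n_post + 1L
        usages <- c(usages, expr_terms(slot))
      }
    }
  }
  ns <- sub(":.*$", "", usages)
  by_ns <- if (length(usages)) {
    agg <- data.frame(namespace = sort(unique(ns)), stringsAsFactors = FALSE)
    agg$total <- vapply(agg$namespace, function(x) sum(ns == x), integer(1L))
    agg$unique <- vapply(agg$namespace, function(x)
      length(unique(usages[ns == x])), integer(1L))
    agg
  } else {
    data.frame(namespace = character(0), total = integer(0),
               unique = integer(0), stringsAsFactors = FALSE)
  }
  list(n_phenotypes = n_phen, n_characters = length(unique(chars)),
       n_states = length(source$states), n_postcomposed = n_post,
       n_incomplete = n_inc, by_namespace = by_ns)
}
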