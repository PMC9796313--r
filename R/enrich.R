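#' Over-representation of ontology terms in a gene set
#'
#' Upper-tail hypergeometric test per term: with `N` universe genes of
#' which `K` carry the term, and a set of `n` genes of which `k` carry it,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Terms annotating
#' fewer than `min_term_size` universe genes are skipped; p-values are
#' Benjamini-Hochberg adjusted across the tested terms.
#'
#' @param gene_set Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of background gene ids.
#' @param annotation Ancestor-closed annotation: named list gene ->
#'   term ids (see [propagate_annotations()]).
#' @param graph An [ontology_graph()] (supplies term names).
#' @param min_term_size Minimum universe annotation count per tested term.
#'   Default 3.
#' @return `data.frame` sorted by `p` with columns `term_id`, `name`, `k`,
#'   `n`, `K`, `N`, `p`, `p_adj`.
#' @export
enrich <- function(gene_set, universe, annotation, graph, min_term_size = 3) {
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  assert_that(length(universe) > 0 && length(gene_set) > 0,
              "empty gene set or universe")
  assert_that(all(gene_set %in% universe),
              "gene set must be a subset of the universe")
  ann <- annotation[intersect(names(annotation), universe)]
  term_genes <- split(
    rep(names(ann), lengths(ann)),
    unlist(ann, use.names = FALSE))
  K <- vapply(term_genes, length, integer(1))
  tested <- names(K)[K >= min_term_size]
  N <- length(universe)
  n <- length(gene_set)
  k <- vapply(term_genes[tested],
              function(gs) length(intersect(gs, gene_set)), integer(1))
  p <- stats::phyper(k - 1, K[tested], N - K[tested], n, lower.tail = FALSE)
  out <- data.frame(
    term_id = tested,
    name = graph$terms$name[match(tested, graph$terms$id)],
    k = as.integer(k), n = n, K = as.integer(K[tested]), N = N,
    p = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster enriched terms by graph distance and name a common parent
#'
#' Enriched terms are agglomerated hierarchically (default average linkage)
#' on their pairwise undirected is_a graph distances and the tree is cut at
#' `cut_distance`; at the default cut of 2, siblings under one parent and
#' parent-child pairs merge. Each cluster is summarized by its deepest
#' common ancestor-or-self (ties broken by lexicographically smallest id);
#' a singleton's representative is the term itself. Terms at infinite
#' distance (disconnected namespaces) never share a cluster.
#'
#' @param term_ids Character vector of (enriched) term ids, length >= 1.
#' @param graph An [ontology_graph()].
#' @param linkage `hclust` agglomeration method. Default `"average"`.
#' @param cut_distance Tree cut height. Default 2.
#' @return `data.frame` with columns `term_id`, `cluster` (integer id) and
#'   `representative` (term id of the common parent).
#' @export
cluster_terms <- function(term_ids, graph, linkage = "average",
                          cut_distance = 2) {
  term_ids <- unique(as.character(term_ids))
  assert_that(length(term_ids) >= 1, "need at least one term")
  if (length(term_ids) == 1) {
    cl <- stats::setNames(1L, term_ids)
  } else {
    D <- term_distance_matrix(graph, term_ids)
    # a sentinel far above any reachable cut keeps disconnected terms apart
    sentinel <- max(D[is.finite(D)], 0) + cut_distance + nrow(D) + 1
    D[!is.finite(D)] <- sentinel
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    cl <- stats::cutree(hc, h = cut_distance)
  }
  rep_of <- vapply(split(names(cl), cl), function(members) {
    self_or_anc <- lapply(members,
                          function(t) c(t, graph$ancestors[[t]]))
    common <- Reduce(intersect, self_or_anc)
    if (length(common) == 0) return(NA_character_)
    dmax <- max(graph$depth[common])
    cand <- sort(common[graph$depth[common] == dmax])
    cand[1]
  }, character(1))
  out <- data.frame(term_id = names(cl), cluster = as.integer(cl),
                    representative = unname(rep_of[as.character(cl)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enrichment with term clustering for every kinetic gene set
#'
#' Runs [enrich()] for each non-empty kinetic class gene set against the
#' annotated universe and clusters the significant terms of each set.
#'
#' @param class_summary Result of [summarize_classes()] (carries the
#'   per-class gene sets).
#' @param annotation Named list gene -> term ids (will be ancestor-closed).
#' @param graph An [ontology_graph()].
#' @param min_term_size Passed to [enrich()].
#' @param p_adj_max Adjusted-p cutoff for terms entering the clustering.
#'   Default 0.05.
#' @param cut_distance Passed to [cluster_terms()].
#' @return Named list per class: list with `enrichment` table and
#'   `clusters` table (or `NULL` when nothing is significant).
#' @export
enrich_classes <- function(class_summary, annotation, graph,
                           min_term_size = 3, p_adj_max = 0.05,
                           cut_distance = 2) {
  closed <- propagate_annotations(annotation, graph)
  universe <- names(closed)[lengths(closed) > 0]
  sets <- attr(class_summary, "gene_sets")
  sets <- sets[setdiff(names(sets), "none")]
  out <- list()
  for (cl in names(sets)) {
    gs <- intersect(sets[[cl]], universe)
    if (length(gs) == 0) next
    et <- enrich(gs, universe, closed, graph, min_term_size)
    sig <- et$term_id[et$p_adj < p_adj_max]
    clu <- if (length(sig) >= 1) {
      cluster_terms(sig, graph, cut_distance = cut_distance)
    } else NULL
    out[[cl]] <- list(enrichment = et, clusters = clu)
  }
  out
}
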