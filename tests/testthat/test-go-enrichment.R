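test_that("annotation closure follows the true-path rule", {
  g <- toy_graph()
  # chain root -> a -> c: a gene on c is implicitly on a and root
  ann <- propagate_annotations(list(gene1 = "c"), g)
  expect_identical(ann$gene1, sort(c("c", "a", "root")))
  # already-closed annotation is unchanged
  ann2 <- propagate_annotations(ann, g)
  expect_identical(ann, ann2)
  # multi-parent term d reaches both a and b
  expect_identical(propagate_annotations(list(x = "d"), g)$x,
                   sort(c("d", "a", "b", "root")))
  expect_warning(propagate_annotations(list(x = c("c", "nope")), g),
                 "unknown")
})

test_that("closure equals the reachability-matrix oracle on random DAGs", {
  for (seed in 1:5) {
    onto <- simulate_ontology(n_terms = 15, genes = paste0("g", 1:8),
                              annotation_density = 0.2, seed = seed)
    g <- onto$graph
    terms <- g$terms$id
    for (gene in names(onto$annotation)) {
      # recover a minimal direct set, then close it both ways
      direct <- onto$annotation[[gene]]
      got <- propagate_annotations(stats::setNames(list(direct), gene), g)[[1]]
      want <- oracle_closure(terms, g$edges, direct)
      expect_identical(got, want)
    }
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked case: N=10, K=4, n=5, k=3 -> 66/252
  universe <- paste0("g", 1:10)
  graph <- ontology_graph(
    terms = data.frame(id = c("root", "t"), name = c("root", "t")),
    edges = data.frame(child = "t", parent = "root"))
  ann <- c(lapply(1:4, function(i) c("t", "root")),
           lapply(5:10, function(i) "root"))
  names(ann) <- universe
  gene_set <- c("g1", "g2", "g3", "g9", "g10")  # k = 3 of the K = 4
  et <- enrich(gene_set, universe, ann, graph, min_term_size = 3)
  row <- et[et$term_id == "t", ]
  expect_identical(c(row$k, row$n, row$K, row$N), c(3L, 5L, 4L, 10L))
  expect_equal(row$p, 66 / 252, tolerance = 1e-12)
  expect_equal(row$p, oracle_hyper_p(10, 4, 5, 3), tolerance = 1e-12)

  # k = 0 and set == universe both force p = 1
  none_set <- paste0("g", 5:9)
  expect_equal(enrich(none_set, universe, ann, graph)$p[
    enrich(none_set, universe, ann, graph)$term_id == "t"], 1)
  full <- enrich(universe, universe, ann, graph)
  expect_true(all(full$p == 1))
})

test_that("the p formula equals subset enumeration for every N <= 12", {
  for (N in c(5, 8, 12)) {
    for (K in c(1, 3, N - 1)) {
      for (n in c(2, N %/% 2)) {
        for (k in 0:min(n, K)) {
          got <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
          expect_equal(got, oracle_hyper_p(N, K, n, k), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("BH adjustment is monotone and matches the step-up decision", {
  set.seed(51)
  p <- runif(50)^2
  adj <- p.adjust(p, "BH")
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_true(all(adj >= p))
  # thresholding the adjusted values reproduces the step-up procedure
  for (alpha in c(0.01, 0.05, 0.2)) {
    ps <- sort(p)
    k <- suppressWarnings(max(which(ps <= alpha * seq_along(ps) / 50)))
    rejected_stepup <- if (is.finite(k)) p <= ps[k] else rep(FALSE, 50)
    expect_identical(adj <= alpha, rejected_stepup)
  }
})

test_that("term distances equal an independent BFS", {
  g <- toy_graph()
  expect_equal(term_distance(g, "c", "c"), 0)
  expect_equal(term_distance(g, "c", "a"), 1)
  expect_equal(term_distance(g, "c", "d"), 2)
  expect_equal(term_distance(g, "c", "e"), 4)  # c-a-d-b-e via d, not root
  for (seed in 1:3) {
    onto <- simulate_ontology(n_terms = 20, genes = "g1", seed = seed)
    gr <- onto$graph
    ids <- sample(gr$terms$id, 6)
    D <- term_distance_matrix(gr, ids)
    for (i in 1:5) {
      for (j in (i + 1):6) {
        expect_equal(D[i, j],
                     oracle_bfs_distance(gr$edges, ids[i], ids[j]))
      }
    }
  }
})

test_that("disconnected terms get infinite distance and separate clusters", {
  g <- ontology_graph(
    terms = data.frame(id = c("r1", "x", "r2", "y"),
                       name = c("r1", "x", "r2", "y")),
    edges = data.frame(child = c("x", "y"), parent = c("r1", "r2")))
  expect_identical(term_distance(g, "x", "y"), Inf)
  cl <- cluster_terms(c("x", "y"), g, cut_distance = 2)
  expect_identical(length(unique(cl$cluster)), 2L)
})

test_that("term clustering merges near terms and names the common parent", {
  g <- toy_graph()
  # a singleton is its own representative
  one <- cluster_terms("c", g)
  expect_identical(one$representative, "c")
  # siblings c and d under a (distance 2, cut 2) merge with representative a
  two <- cluster_terms(c("c", "d"), g, cut_distance = 2)
  expect_identical(unique(two$cluster), 1L)
  expect_identical(unique(two$representative), "a")
  # e and f are siblings under b; c joins neither at cut 2 (d(c,e) = 4)
  three <- cluster_terms(c("c", "e", "f"), g, cut_distance = 2)
  expect_identical(length(unique(three$cluster)), 2L)
  expect_identical(three$representative[three$term_id == "e"], "b")
  expect_identical(three$representative[three$term_id == "c"], "c")
})

test_that("clustering matches a direct agglomeration oracle", {
  g <- toy_graph()
  terms <- c("a", "b", "c", "d", "e", "f")
  D <- term_distance_matrix(g, terms)
  for (cut in c(1, 2, 3)) {
    got <- partition_from_clusters(cluster_terms(terms, g,
                                                 cut_distance = cut))
    want <- canonical_partition(oracle_average_linkage(D, cut))
    expect_identical(got, want, label = paste("cut", cut))
  }
})

test_that("every representative is an ancestor-or-self of its cluster", {
  for (seed in 1:5) {
    onto <- simulate_ontology(n_terms = 25, genes = "g1", seed = seed)
    g <- onto$graph
    picked <- sample(g$terms$id, 8)
    cl <- cluster_terms(picked, g, cut_distance = 2)
    for (i in seq_len(nrow(cl))) {
      rep_t <- cl$representative[i]
      t <- cl$term_id[i]
      expect_true(rep_t == t || rep_t %in% g$ancestors[[t]])
    }
  }
})

test_that("a set built from one term's genes recovers that term on top", {
  onto <- simulate_ontology(n_terms = 20, genes = paste0("g", 1:60),
                            annotation_density = 0.15, seed = 8)
  g <- onto$graph
  ann <- onto$annotation
  universe <- names(ann)
  # pick a term annotating 5-20 universe genes, use exactly its genes
  term_genes <- split(rep(names(ann), lengths(ann)),
                      unlist(ann, use.names = FALSE))
  sizes <- lengths(term_genes)
  cand <- names(sizes)[sizes >= 5 & sizes <= 20 & g$depth[names(sizes)] > 0]
  target <- cand[which.max(g$depth[cand])]
  et <- enrich(term_genes[[target]], universe, ann, g)
  top <- et$term_id[1]
  expect_true(top == target || top %in% c(g$ancestors[[target]]))
})
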