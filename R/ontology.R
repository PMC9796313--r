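#' Construct an ontology graph from terms and is_a edges
#'
#' A directed acyclic graph of terms linked child -> parent by `is_a`.
#' Ancestor sets and term depths (shortest path to a root, in edges) are
#' precomputed at construction.
#'
#' @param terms `data.frame` with columns `id` and `name`.
#' @param edges `data.frame` with columns `child` and `parent` (term ids).
#' @return Object of class `"ontology_graph"`: list with `terms`, `edges`,
#'   `roots`, `ancestors` (named list, excluding self), `depth` (named
#'   integer vector) and the internal `igraph`.
#' @export
ontology_graph <- function(terms, edges) {
  assert_that(is.data.frame(terms) && all(c("id", "name") %in% names(terms)),
              "terms must have columns id, name")
  terms$id <- as.character(terms$id)
  terms$name <- as.character(terms$name)
  assert_that(!anyDuplicated(terms$id), "duplicate term ids")
  if (nrow(edges) > 0) {
    assert_that(all(c("child", "parent") %in% names(edges)),
                "edges must have columns child, parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    unknown <- setdiff(c(edges$child, edges$parent), terms$id)
    assert_that(length(unknown) == 0,
                paste("edge references unknown term(s):",
                      paste(unknown, collapse = ", ")))
  } else {
    edges <- data.frame(child = character(0), parent = character(0))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id)
  assert_that(igraph::is_dag(g), "is_a relations contain a cycle")
  roots <- terms$id[!(terms$id %in% edges$child)]
  assert_that(length(roots) >= 1, "ontology has no root term")

  anc <- lapply(terms$id, function(t) {
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
  })
  names(anc) <- terms$id

  dmat <- igraph::distances(g, v = terms$id, to = roots, mode = "out")
  depth <- apply(dmat, 1, min)
  names(depth) <- terms$id

  structure(list(terms = terms, edges = edges, roots = roots,
                 ancestors = anc, depth = depth, graph = g),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,", nrow(x$edges),
      "is_a edges,", length(x$roots), "root(s), max depth",
      max(x$depth[is.finite(x$depth)]), "\n")
  invisible(x)
}

#' Ancestor terms (excluding the term itself)
#'
#' @param graph An [ontology_graph()].
#' @param term Term id.
#' @return Character vector of ancestor ids.
#' @export
term_ancestors <- function(graph, term) {
  assert_that(term %in% graph$terms$id, paste("unknown term:", term))
  graph$ancestors[[term]]
}

#' Graph distance between two terms
#'
#' Length of the shortest path between two terms treating is_a edges as
#' undirected; terms in disconnected components get `Inf`.
#'
#' @param graph An [ontology_graph()].
#' @param t1,t2 Term ids.
#' @return Non-negative number of edges (possibly `Inf`).
#' @export
term_distance <- function(graph, t1, t2) {
  assert_that(all(c(t1, t2) %in% graph$terms$id), "unknown term id")
  as.numeric(igraph::distances(graph$graph, v = t1, to = t2, mode = "all"))
}

#' Pairwise graph-distance matrix for a set of terms
#'
#' @param graph An [ontology_graph()].
#' @param term_ids Character vector of term ids.
#' @return Symmetric matrix of undirected shortest-path distances.
#' @export
term_distance_matrix <- function(graph, term_ids) {
  assert_that(all(term_ids %in% graph$terms$id), "unknown term id")
  D <- igraph::distances(graph$graph, v = term_ids, to = term_ids,
                         mode = "all")
  D[term_ids, term_ids, drop = FALSE]
}

#' Close gene annotations under ontology ancestry (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. Annotations to unknown terms are skipped with a warning.
#'
#' @param annotation Named list: gene id -> character vector of term ids.
#' @param graph An [ontology_graph()].
#' @return Named list: gene id -> ancestor-closed sorted term ids.
#' @export
propagate_annotations <- function(annotation, graph) {
  known <- graph$terms$id
  n_skipped <- 0
  out <- lapply(annotation, function(ts) {
    ts <- unique(as.character(ts))
    bad <- !(ts %in% known)
    n_skipped <<- n_skipped + sum(bad)
    ts <- ts[!bad]
    if (length(ts) == 0) return(character(0))
    sort(unique(c(ts, unlist(graph$ancestors[ts], use.names = FALSE))))
  })
  if (n_skipped > 0) {
    warning("skipped ", n_skipped, " annotation(s) to unknown terms",
            call. = FALSE)
  }
  out
}
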