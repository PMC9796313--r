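# Independent brute-force oracles. Each re-derives a quantity by the most
# direct means available (enumeration, per-base bitmaps, explicit sorting)
# and is kept free of the package's own computational paths.

# --- trimmed weighted mean of M-values, computed by explicit sorting -------
oracle_tmm_pair <- function(obs, ref, logratio_trim = 0.30, abs_trim = 0.05) {
  nO <- sum(obs); nR <- sum(ref)
  keep0 <- obs > 0 & ref > 0
  M <- log2((obs / nO) / (ref / nR))[keep0]
  A <- ((log2(obs / nO) + log2(ref / nR)) / 2)[keep0]
  w <- ((nO - obs) / nO / obs + (nR - ref) / nR / ref)[keep0]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  kM <- floor(n * logratio_trim)
  kA <- floor(n * abs_trim)
  in_band <- function(v, k) {
    ord <- sort(v)
    lo <- ord[k + 1]; hi <- ord[n - k]
    v >= lo & v <= hi
  }
  keep <- in_band(M, kM) & in_band(A, kA)
  2^(sum(M[keep] * (1 / w[keep])) / sum(1 / w[keep]))
}

# --- exon-union length by per-base occupancy bitmap ------------------------
oracle_union_length <- function(starts, ends, max_coord = 10000) {
  occupied <- logical(max_coord)
  for (i in seq_along(starts)) occupied[starts[i]:ends[i]] <- TRUE
  sum(occupied)
}

# --- upper-tail hypergeometric by subset enumeration -----------------------
oracle_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(subsets, 2, function(s) sum(s %in% marked))
  sum(overlaps >= k) / ncol(subsets)
}

# --- shortest undirected path by hand-rolled BFS ---------------------------
oracle_bfs_distance <- function(edges, t1, t2) {
  if (t1 == t2) return(0)
  adj <- list()
  add <- function(a, b) adj[[a]] <<- union(adj[[a]], b)
  for (i in seq_len(nrow(edges))) {
    add(edges$child[i], edges$parent[i])
    add(edges$parent[i], edges$child[i])
  }
  dist <- c(stats::setNames(0, t1))
  frontier <- t1
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (!u %in% names(dist)) {
          dist[u] <- dist[v] + 1
          if (u == t2) return(unname(dist[u]))
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

# --- ancestor closure by boolean reachability matrix -----------------------
oracle_closure <- function(terms, edges, direct_terms) {
  n <- length(terms)
  R <- diag(TRUE, n)
  dimnames(R) <- list(terms, terms)
  for (i in seq_len(nrow(edges))) R[edges$child[i], edges$parent[i]] <- TRUE
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) break
    R <- R2
  }
  reach <- R > 0
  sort(unique(unlist(lapply(direct_terms,
                            function(t) terms[reach[t, ]]))))
}

# --- average-linkage agglomeration by direct pairwise merging --------------
# merges the closest pair of clusters while the minimum average pairwise
# distance is <= cut; returns cluster membership as a list of id vectors
oracle_average_linkage <- function(D, cut) {
  clusters <- as.list(rownames(D))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, sort)
}

# canonical form for comparing partitions
canonical_partition <- function(sets) {
  sets <- unname(lapply(sets, sort))
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# partition from a cluster_terms() result
partition_from_clusters <- function(df) {
  canonical_partition(split(df$term_id, df$cluster))
}

# --- Spearman rho and exact permutation p by direct rank arithmetic --------
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact permutation p over all n! orderings (n <= 8)
oracle_exact_perm_p <- function(x, y) {
  n <- length(x)
  perms <- all_permutations(n)
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- 0
  for (i in seq_len(nrow(perms))) {
    if (abs(oracle_spearman_rho(x, y[perms[i, ]])) >= obs - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / nrow(perms)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# --- small fixture builders ------------------------------------------------
# one-row grid pairing an analyte profile x with an absorbance profile y
grid_from_xy <- function(x, y, analyte = "ORS") {
  n <- length(x)
  spatial_grid(data.frame(
    row = rep(1, 2 * n), col = rep(seq_len(n), 2),
    analyte = rep(c(analyte, "absorbance_400nm"), each = n),
    value = c(x, y)))
}

toy_experiment <- function(counts, times = NULL) {
  n <- ncol(counts)
  if (is.null(times)) times <- rep(c("0", "0.5h", "3h"), length.out = n)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  design <- data.frame(sample_id = colnames(counts), time = times,
                       replicate = stats::ave(seq_len(n), times, FUN = seq_along))
  count_experiment(counts, design)
}

# a small fixed DAG used across ontology tests:
#        root
#       /    \
#      a      b
#     / \    / \
#    c   d  e   f   (d also is_a b)
toy_graph <- function() {
  ontology_graph(
    terms = data.frame(id = c("root", "a", "b", "c", "d", "e", "f"),
                       name = paste("term", 1:7)),
    edges = data.frame(
      child = c("a", "b", "c", "d", "d", "e", "f"),
      parent = c("root", "root", "a", "a", "b", "b", "b")))
}
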