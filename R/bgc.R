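#' Per-biosynthetic-gene-cluster regulation summary
#'
#' For each cluster of a membership table, counts the member genes called
#' up (and down) in each of the two contrast windows and the total number
#' regulated in either window (the union of the two window sets — forced by
#' the reference table arithmetic, where disjoint window sets add and
#' nested ones do not). Genes absent from the calls table count as not
#' regulated; a cluster with no gene in the calls table yields a zero row
#' with a warning.
#'
#' @param per_gene_calls `data.frame` with columns `gene_id`, `call1`,
#'   `call2` (values `up`/`down`/`ns`), e.g. from [classify_genes()].
#' @param bgc_membership `data.frame` with columns `cluster_id`, `gene_id`.
#' @return `data.frame` with one row per cluster: `cluster_id`,
#'   `up_total`, `up_w1`, `up_w2`, `down_total`, `down_w1`, `down_w2`,
#'   `n_genes_total`, plus display columns `up` and `down` formatted as
#'   `"total (w1, w2)"`.
#' @export
summarize_bgc <- function(per_gene_calls, bgc_membership) {
  assert_that(all(c("gene_id", "call1", "call2") %in% names(per_gene_calls)),
              "per_gene_calls needs columns gene_id, call1, call2")
  assert_that(all(c("cluster_id", "gene_id") %in% names(bgc_membership)),
              "bgc_membership needs columns cluster_id, gene_id")
  calls <- per_gene_calls
  clusters <- split(as.character(bgc_membership$gene_id),
                    as.character(bgc_membership$cluster_id))
  rows <- lapply(names(clusters), function(cid) {
    genes <- unique(clusters[[cid]])
    idx <- match(genes, calls$gene_id)
    present <- !is.na(idx)
    if (!any(present)) {
      warning("cluster '", cid, "' has no gene in the calls table; ",
              "zero row emitted", call. = FALSE)
    }
    c1 <- ifelse(present, calls$call1[idx], "ns")
    c2 <- ifelse(present, calls$call2[idx], "ns")
    up1 <- genes[c1 == "up"];   up2 <- genes[c2 == "up"]
    dn1 <- genes[c1 == "down"]; dn2 <- genes[c2 == "down"]
    data.frame(cluster_id = cid,
               up_total = length(union(up1, up2)),
               up_w1 = length(up1), up_w2 = length(up2),
               down_total = length(union(dn1, dn2)),
               down_w1 = length(dn1), down_w2 = length(dn2),
               n_genes_total = length(genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fmt <- function(total, w1, w2) {
    ifelse(total == 0, "0", sprintf("%d (%d, %d)", total, w1, w2))
  }
  out$up <- fmt(out$up_total, out$up_w1, out$up_w2)
  out$down <- fmt(out$down_total, out$down_w1, out$down_w2)
  rownames(out) <- NULL
  out
}
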