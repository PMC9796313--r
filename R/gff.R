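#' Exon-union gene lengths from a GFF3 annotation
#'
#' For each gene, the exon intervals of all its transcripts are merged
#' (union of 1-based closed intervals, strand ignored) and the merged
#' widths summed — the "per kilobase of exon" denominator of RPKM. Exons
#' are assigned to genes by following `Parent` attributes transitively
#' (exon -> mRNA -> gene); exons whose `Parent` is directly a gene are also
#' accepted. Exons without a resolvable gene are skipped with a warning
#' reporting their number.
#'
#' @param gff3_path Path to the GFF3 file.
#' @param feature Feature type measured. Default `"exon"`.
#' @param gene_types Feature types treated as genes when resolving
#'   parentage. Default `"gene"`.
#' @return Named numeric vector: gene id -> exon-union length (bp).
#' @export
gene_lengths_from_gff3 <- function(gff3_path, feature = "exon",
                                   gene_types = "gene") {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  types <- as.character(md$type)
  # first Parent per feature; GFF3 allows several, the first resolves the gene
  parents <- vapply(as.list(md$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  parent_of <- stats::setNames(parents, ids)
  type_of <- stats::setNames(types, ids)

  resolve_gene <- function(pid) {
    seen <- character(0)
    while (!is.na(pid) && !(pid %in% seen)) {
      if (!is.na(type_of[pid]) && type_of[pid] %in% gene_types) return(pid)
      seen <- c(seen, pid)
      pid <- if (pid %in% names(parent_of)) parent_of[[pid]] else NA_character_
    }
    NA_character_
  }

  is_exon <- types == feature
  exons <- gr[is_exon]
  exon_parent <- parents[is_exon]
  gene_id <- vapply(exon_parent, resolve_gene, character(1), USE.NAMES = FALSE)
  n_orphan <- sum(is.na(gene_id))
  if (n_orphan > 0) {
    warning(n_orphan, " ", feature,
            " feature(s) without a resolvable gene were skipped",
            call. = FALSE)
  }
  keep <- !is.na(gene_id)
  exons <- exons[keep]
  gene_id <- gene_id[keep]
  assert_that(length(exons) > 0, "no exon could be assigned to a gene")
  by_gene <- split(GenomicRanges::ranges(exons), gene_id)
  vapply(by_gene,
         function(r) sum(IRanges::width(IRanges::reduce(r))),
         numeric(1))
}
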