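#' Construct a validated count experiment
#'
#' Bundles a gene-by-sample integer count matrix with its sample design
#' (time point and replicate) and, optionally, exon-union gene lengths.
#' This is the entry object of the pipeline: every sample in the design must
#' be a column of the matrix and vice versa, gene identifiers must be unique,
#' and counts must be non-negative integers.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param design `data.frame` with columns `sample_id`, `time` (one of
#'   `"0"`, `"0.5h"`, `"3h"`) and `replicate`.
#' @param gene_lengths Optional named numeric vector of exon-union lengths
#'   in base pairs; names are gene ids.
#' @return An object of class `"count_experiment"`: a list with elements
#'   `counts`, `design` and `gene_lengths`.
#' @export
count_experiment <- function(counts, design, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must have gene ids as rownames and sample ids as colnames")
  assert_that(!anyDuplicated(rownames(counts)), "duplicate gene ids in counts")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate sample ids in counts")
  assert_that(is.numeric(counts) && all(is.finite(counts)),
              "counts must be finite and numeric")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(all(counts == round(counts)),
              "counts must be integers (fractional value found)")
  storage.mode(counts) <- "double"

  assert_that(is.data.frame(design) &&
                all(c("sample_id", "time", "replicate") %in% names(design)),
              "design must have columns sample_id, time, replicate")
  design$sample_id <- as.character(design$sample_id)
  design$time <- as.character(design$time)
  assert_that(all(design$time %in% TIME_POINTS),
              paste0("design times must be one of: ",
                     paste(TIME_POINTS, collapse = ", ")))
  assert_that(!anyDuplicated(design$sample_id), "duplicate sample ids in design")
  missing_in_counts <- setdiff(design$sample_id, colnames(counts))
  missing_in_design <- setdiff(colnames(counts), design$sample_id)
  assert_that(length(missing_in_counts) == 0,
              paste("design samples absent from count matrix:",
                    paste(missing_in_counts, collapse = ", ")))
  assert_that(length(missing_in_design) == 0,
              paste("count matrix samples absent from design:",
                    paste(missing_in_design, collapse = ", ")))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL

  if (!is.null(gene_lengths)) {
    assert_that(!is.null(names(gene_lengths)), "gene_lengths must be named")
    assert_that(all(gene_lengths >= 1), "gene lengths must be >= 1 bp")
  }

  structure(list(counts = counts, design = design,
                 gene_lengths = gene_lengths),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("count_experiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("time points:",
      paste(sprintf("%s (n=%d)", names(table(x$design$time)),
                    as.integer(table(x$design$time))), collapse = ", "), "\n")
  if (!is.null(x$gene_lengths)) {
    cat("gene lengths present for", length(x$gene_lengths), "genes\n")
  }
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

#' Cell-means design matrix for the three time points
#'
#' One indicator column per time point, so the two sequential contrasts are
#' plain differences of fitted cell means.
#'
#' @param design Design `data.frame` as in [count_experiment()].
#' @return Numeric matrix with one row per sample and columns
#'   `t0`, `t30m`, `t3h`.
#' @export
design_matrix <- function(design) {
  time <- factor(design$time, levels = TIME_POINTS)
  X <- stats::model.matrix(~ 0 + time)
  colnames(X) <- c("t0", "t30m", "t3h")[seq_len(ncol(X))]
  rownames(X) <- design$sample_id
  X
}

#' The two sequential contrast vectors
#'
#' Later time minus earlier time, so positive log2 fold change means
#' upregulation after treatment: 30 min vs 0, and 3 h vs 30 min.
#'
#' @param X Design matrix from [design_matrix()] (used for dimension and
#'   column names).
#' @return Matrix with one column per contrast.
#' @export
sequential_contrasts <- function(X) {
  p <- ncol(X)
  assert_that(p == 3, "sequential contrasts require the three-time-point design")
  C <- cbind(c(-1, 1, 0), c(0, -1, 1))
  rownames(C) <- colnames(X)
  colnames(C) <- CONTRAST_NAMES
  C
}
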