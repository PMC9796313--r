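#' The eight kinetic response classes
#'
#' Over two sequential contrasts (0 -> 30 min, 30 min -> 3 h) a gene's
#' ternary regulation calls (up / down / ns) define nine sign patterns.
#' The eight non-null patterns name the kinetic behaviours: immediately
#' regulated to steady state (A1 up, A2 down), continuously further
#' regulated (B1, B2), delayed (C1, C2) and transient (D1, D2); (ns, ns)
#' is `"none"`.
#'
#' @return `data.frame` with columns `class`, `call1`, `call2`,
#'   `description` enumerating the full truth table.
#' @export
kinetic_class_table <- function() {
  data.frame(
    class = c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2", "none"),
    call1 = c("up", "down", "up", "down", "ns", "ns", "up", "down", "ns"),
    call2 = c("ns", "ns", "up", "down", "up", "down", "down", "up", "ns"),
    description = c(
      "immediately upregulated to steady state",
      "immediately downregulated to steady state",
      "immediately upregulated and continuously further upregulated",
      "immediately downregulated and continuously further downregulated",
      "delayed upregulated",
      "delayed downregulated",
      "transiently upregulated",
      "transiently downregulated",
      "not regulated"),
    stringsAsFactors = FALSE
  )
}

#' Ternary regulation call from effect size and p-value
#'
#' A gene counts as regulated in a contrast only when both criteria agree:
#' absolute log2 fold change strictly greater than `lfc_min` AND p-value
#' strictly below `p_max`. When the two criteria disagree (large fold change
#' but weak evidence, or significant p but small fold change) no regulation
#' is called. Both inequalities are strict, so values exactly at the
#' boundary (|log2FC| = 1, p = 0.01 at the defaults) are `ns`.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lfc_min Minimum absolute log2 fold change (exclusive). Default 1.
#' @param p_max Maximum p-value (exclusive). Default 0.01.
#' @return Character vector in `{"up", "down", "ns"}`. `NA`/`NaN` inputs
#'   yield `"ns"` with a warning.
#' @export
call_regulation <- function(log2fc, p, lfc_min = 1.0, p_max = 0.01) {
  assert_that(length(log2fc) == length(p), "log2fc and p lengths differ")
  assert_that(lfc_min >= 0 && p_max >= 0, "thresholds must be non-negative")
  bad <- !is.finite(log2fc) | !is.finite(p)
  if (any(bad)) {
    warning(sum(bad), " non-finite input(s) called 'ns'", call. = FALSE)
  }
  ok <- !bad & p >= 0 & p <= 1
  if (any(!bad & !ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  call <- rep("ns", length(log2fc))
  sig <- ok & p < p_max & abs(log2fc) > lfc_min
  call[sig & log2fc > 0] <- "up"
  call[sig & log2fc < 0] <- "down"
  call
}

#' Kinetic class from the two per-contrast regulation calls
#'
#' Exact lookup of the (call1, call2) pattern in the truth table of
#' [kinetic_class_table()]. Calls must come from the two contrasts in
#' temporal order (0 -> 30 min first, 30 min -> 3 h second).
#'
#' @param call1,call2 Character vectors in `{"up", "down", "ns"}`.
#' @return Character vector of class labels
#'   (`A1`,`A2`,`B1`,`B2`,`C1`,`C2`,`D1`,`D2`,`none`).
#' @export
classify_kinetics <- function(call1, call2) {
  assert_that(length(call1) == length(call2), "call vectors differ in length")
  valid <- c("up", "down", "ns")
  assert_that(all(call1 %in% valid) && all(call2 %in% valid),
              "calls must be 'up', 'down' or 'ns'")
  tab <- kinetic_class_table()
  key <- paste(call1, call2, sep = "|")
  tab_key <- paste(tab$call1, tab$call2, sep = "|")
  tab$class[match(key, tab_key)]
}

#' Tabulate kinetic classes with their gene lists
#'
#' @param classes Character vector of class labels, named by gene id (or
#'   accompanied by `genes`).
#' @param genes Optional character vector of gene ids, same length.
#' @return `data.frame` with one row per class label (all nine, in canonical
#'   order), columns `class`, `n_genes`, `genes` (comma-separated) and an
#'   attribute `"gene_sets"`: a named list of gene id vectors.
#' @export
summarize_classes <- function(classes, genes = names(classes)) {
  if (is.null(genes)) genes <- paste0("gene", seq_along(classes))
  assert_that(length(genes) == length(classes),
              "one classification per gene required")
  labels <- kinetic_class_table()$class
  assert_that(all(classes %in% labels), "unknown class label")
  sets <- lapply(labels, function(cl) sort(genes[classes == cl]))
  names(sets) <- labels
  out <- data.frame(
    class = labels,
    n_genes = vapply(sets, length, integer(1)),
    genes = vapply(sets, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gene_sets") <- sets
  out
}

#' Per-gene kinetic classification of a differential-expression result
#'
#' Convenience wrapper: applies [call_regulation()] to each of the two
#' contrast tables and [classify_kinetics()] to the pair of calls.
#'
#' @param contrast_results List of two per-contrast `data.frame`s (as
#'   returned by [test_contrasts()]), in temporal order; each must have
#'   columns `gene_id`, `log2fc`, `p`.
#' @param lfc_min,p_max Thresholds passed to [call_regulation()].
#' @return `data.frame` with columns `gene_id`, `call1`, `call2`, `class`.
#' @export
classify_genes <- function(contrast_results, lfc_min = 1.0, p_max = 0.01) {
  assert_that(is.list(contrast_results) && length(contrast_results) == 2,
              "expected results for exactly two contrasts")
  r1 <- contrast_results[[1]]
  r2 <- contrast_results[[2]]
  assert_that(identical(r1$gene_id, r2$gene_id),
              "contrast tables must cover the same genes in the same order")
  call1 <- call_regulation(r1$log2fc, r1$p, lfc_min, p_max)
  call2 <- call_regulation(r2$log2fc, r2$p, lfc_min, p_max)
  data.frame(gene_id = r1$gene_id, call1 = call1, call2 = call2,
             class = classify_kinetics(call1, call2),
             stringsAsFactors = FALSE)
}
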