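#' Construct a validated spatial confrontation-assay grid
#'
#' Long-format lattice of agar blocks cut from a co-culture plate: each
#' record is one block (1-based `row`, `col`; row 1 = top of the plate
#' photograph, column 1 = left) carrying one analyte's value — a metabolite
#' concentration or the pigment absorbance at 400 nm (analyte name
#' `"absorbance_400nm"`). Missing blocks are allowed and tracked per
#' analyte.
#'
#' @param blocks `data.frame` with columns `row`, `col`, `analyte`,
#'   `value` (values must be non-negative).
#' @return Object of class `"spatial_grid"`: list with `blocks`,
#'   `analytes`, `n_rows`, `n_cols`.
#' @export
spatial_grid <- function(blocks) {
  assert_that(is.data.frame(blocks) &&
                all(c("row", "col", "analyte", "value") %in% names(blocks)),
              "grid needs columns row, col, analyte, value")
  blocks$row <- as.integer(blocks$row)
  blocks$col <- as.integer(blocks$col)
  blocks$analyte <- as.character(blocks$analyte)
  blocks$value <- as.numeric(blocks$value)
  assert_that(all(blocks$row >= 1) && all(blocks$col >= 1),
              "row/col indices are 1-based")
  assert_that(all(is.finite(blocks$value)) && all(blocks$value >= 0),
              "values must be finite and non-negative")
  key <- paste(blocks$row, blocks$col, blocks$analyte)
  assert_that(!anyDuplicated(key), "duplicate (row, col, analyte) record")
  structure(list(blocks = blocks,
                 analytes = sort(unique(blocks$analyte)),
                 n_rows = max(blocks$row), n_cols = max(blocks$col)),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat("spatial_grid:", x$n_rows, "x", x$n_cols, "blocks;",
      length(x$analytes), "analyte(s):",
      paste(x$analytes, collapse = ", "), "\n")
  invisible(x)
}

#' Row-by-column value matrix for one analyte
#'
#' @param grid A [spatial_grid()].
#' @param analyte Analyte name.
#' @return `n_rows` x `n_cols` matrix; absent blocks are `NA`.
#' @export
grid_matrix <- function(grid, analyte) {
  assert_that(analyte %in% grid$analytes,
              paste("unknown analyte:", analyte))
  b <- grid$blocks[grid$blocks$analyte == analyte, , drop = FALSE]
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols,
              dimnames = list(paste0("row", seq_len(grid$n_rows)),
                              paste0("col", seq_len(grid$n_cols))))
  m[cbind(b$row, b$col)] <- b$value
  m
}

# paired complete block values of two analytes
paired_values <- function(grid, a1, a2) {
  m1 <- grid_matrix(grid, a1)
  m2 <- grid_matrix(grid, a2)
  ok <- is.finite(m1) & is.finite(m2)
  list(x = m1[ok], y = m2[ok], n = sum(ok))
}

#' Rank association of an analyte with the reference channel
#'
#' Spearman correlation across blocks (average ranks for ties), with a
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df and, optionally, a
#' permutation p-value with add-one correction. Missing blocks are dropped
#' pairwise; at least 4 complete paired blocks are required.
#'
#' @param grid A [spatial_grid()].
#' @param analyte Analyte name.
#' @param reference Reference channel. Default `"absorbance_400nm"`.
#' @param n_perm Number of permutations (0 = none).
#' @param seed Seed for the permutation draw.
#' @return One-row `data.frame`: `analyte`, `n`, `rho`, `p`, `perm_p`
#'   (`NA` when `n_perm = 0`), `degenerate` (`TRUE` when a variable had
#'   zero rank variance, in which case `rho` is `NA`).
#' @export
spearman_association <- function(grid, analyte,
                                 reference = "absorbance_400nm",
                                 n_perm = 0, seed = NULL) {
  pv <- paired_values(grid, analyte, reference)
  assert_that(pv$n >= 4, "need at least 4 complete paired blocks")
  if (stats::sd(pv$x) == 0 || stats::sd(pv$y) == 0) {
    warning("zero variance in '", analyte, "' or '", reference,
            "': rho undefined", call. = FALSE)
    return(data.frame(analyte = analyte, n = pv$n, rho = NA_real_,
                      p = NA_real_, perm_p = NA_real_, degenerate = TRUE))
  }
  rho <- stats::cor(pv$x, pv$y, method = "spearman")
  n <- pv$n
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  perm_p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(derive_seed(seed, "perm"))
    rx <- rank(pv$x)
    ry <- rank(pv$y)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r <- stats::cor(rx, sample(ry))
      if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    perm_p <- (1 + hits) / (n_perm + 1)
  }
  data.frame(analyte = analyte, n = n, rho = rho, p = p, perm_p = perm_p,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Pairwise Spearman correlation matrix over analytes
#'
#' @param grid A [spatial_grid()].
#' @param analytes Analyte names (>= 2). Default: all analytes in the grid.
#' @return Symmetric matrix with unit diagonal; entries are `NA` where a
#'   pair is degenerate.
#' @export
correlation_matrix <- function(grid, analytes = grid$analytes) {
  assert_that(length(analytes) >= 2, "need at least 2 analytes")
  k <- length(analytes)
  M <- diag(1, k)
  dimnames(M) <- list(analytes, analytes)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- paired_values(grid, analytes[i], analytes[j])
      r <- if (pv$n >= 2 && stats::sd(pv$x) > 0 && stats::sd(pv$y) > 0) {
        stats::cor(pv$x, pv$y, method = "spearman")
      } else NA_real_
      M[i, j] <- M[j, i] <- r
    }
  }
  M
}
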