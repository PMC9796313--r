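#' Filter genes with insufficient counts
#'
#' Keeps genes whose counts-per-million reach `min_cpm` in at least
#' `min_samples` samples (CPM computed on raw library sizes). The defaults
#' (1 CPM in 2 samples) are a conventional mild filter for three-replicate
#' bulk designs; the decision is logged via `message()`.
#'
#' @param experiment A [count_experiment()].
#' @param min_cpm Minimum counts-per-million (inclusive). Default 1.
#' @param min_samples Minimum number of samples reaching `min_cpm`
#'   (inclusive). Default 2.
#' @return A filtered [count_experiment()].
#' @export
filter_low_counts <- function(experiment, min_cpm = 1, min_samples = 2) {
  assert_that(min_cpm >= 0 && min_samples >= 0, "thresholds must be >= 0")
  counts <- experiment$counts
  lib <- colSums(counts)
  cpm <- t(t(counts) / lib * 1e6)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  message("filter_low_counts: kept ", sum(keep), " of ", nrow(counts),
          " genes (min_cpm=", min_cpm, ", min_samples=", min_samples, ")")
  lengths <- experiment$gene_lengths
  if (!is.null(lengths)) {
    lengths <- lengths[intersect(names(lengths), rownames(counts)[keep])]
  }
  count_experiment(counts[keep, , drop = FALSE], experiment$design, lengths)
}

# 75th percentile of library-size-scaled counts, used to pick the TMM
# reference sample
upper_quartile <- function(counts, lib) {
  vapply(seq_len(ncol(counts)),
         function(j) stats::quantile(counts[, j] / lib[j], probs = 0.75,
                                     names = FALSE),
         numeric(1))
}

# Pairwise trimmed-mean-of-M factor of sample `obs` against `ref`
tmm_pair <- function(obs, ref, logratio_trim, abs_trim) {
  nO <- sum(obs)
  nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))          # M: log fold of proportions
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2  # A: average log abundance
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref  # binomial var approx
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  if (!any(fin)) return(NA_real_)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE)
  f <- 2^f
  if (!is.finite(f)) f <- 1
  f
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample normalization robust to composition bias. The reference
#' sample is the one whose upper quartile of library-size-scaled counts is
#' closest to the mean upper quartile. For each other sample, gene-wise
#' log2 ratios of proportions against the reference (M) and average log2
#' abundances (A) are computed over genes positive in both samples, the M
#' distribution is trimmed by `logratio_trim` in each tail and the A
#' distribution by `abs_trim` in each tail, and the factor is two to the
#' precision-weighted mean of the retained M values (weights are the inverse
#' delta-method binomial variances). Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Gene-by-sample count matrix (>= 2 samples, positive
#'   library sizes).
#' @param logratio_trim Fraction trimmed from each tail of M. Default 0.30.
#' @param abs_trim Fraction trimmed from each tail of A. Default 0.05.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) >= 2, "TMM needs at least two samples")
  lib <- colSums(counts)
  assert_that(all(lib > 0), "every sample needs a positive library size")
  uq <- upper_quartile(counts, lib)
  ref_idx <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_idx) return(1)
    fj <- tmm_pair(counts[, j], counts[, ref_idx], logratio_trim, abs_trim)
    if (is.na(fj)) {
      warning("sample ", colnames(counts)[j],
              " shares no positive gene with the reference; factor set to 1",
              call. = FALSE)
      fj <- 1
    }
    fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million
#'
#' `log2((count + prior_count) / (effective_size + 1) * 1e6)`, the
#' transform feeding the precision-weighted linear models. The prior count
#' keeps zeros finite.
#'
#' @param counts Gene-by-sample count matrix.
#' @param effective_lib_sizes Per-sample effective library sizes (raw size
#'   times TMM factor). Defaults to raw column sums.
#' @param prior_count Pseudo-count added to each observation. Default 0.5.
#' @return Matrix of log2-CPM values, all finite.
#' @export
log_cpm <- function(counts, effective_lib_sizes = colSums(counts),
                    prior_count = 0.5) {
  counts <- as.matrix(counts)
  assert_that(all(effective_lib_sizes > 0), "effective sizes must be > 0")
  assert_that(length(effective_lib_sizes) == ncol(counts),
              "one effective size per sample required")
  t(log2(t(counts + prior_count) / (effective_lib_sizes + 1) * 1e6))
}

#' Reads per kilobase of exon per million library reads
#'
#' `(count + prior_count) / (length/1000) / (lib_size/1e6)`, optionally on
#' the log2 scale (the scale expression levels are reported on). Genes
#' without a length get missing values.
#'
#' @param counts Gene-by-sample count matrix.
#' @param lib_sizes Per-sample library sizes. Defaults to raw column sums;
#'   pass TMM-effective sizes to normalize for composition as well.
#' @param gene_lengths Named numeric vector of exon-union lengths (bp).
#' @param prior_count Pseudo-count. Default 0.5.
#' @param log Return log2 values? Default `TRUE`.
#' @return Matrix of (log2-)RPKM values; rows without a known length are
#'   `NA`.
#' @export
rpkm <- function(counts, lib_sizes = colSums(counts), gene_lengths,
                 prior_count = 0.5, log = TRUE) {
  counts <- as.matrix(counts)
  assert_that(!is.null(names(gene_lengths)), "gene_lengths must be named")
  len <- gene_lengths[rownames(counts)]
  miss <- is.na(len)
  if (any(miss)) {
    warning(sum(miss), " gene(s) without length; RPKM reported as NA",
            call. = FALSE)
  }
  x <- t(t(counts + prior_count) / (lib_sizes / 1e6)) / (len / 1000)
  if (log) x <- log2(x)
  x
}

#' Observation-level precision weights from the mean-variance trend
#'
#' Count data are heteroscedastic on the log scale: low-abundance genes have
#' larger log-CPM variance. Each gene is fit by ordinary least squares on
#' the design, the square root of the residual standard deviation is
#' smoothed against the gene's average log-CPM (lowess, span `span`), and
#' each observation receives weight `predicted_sd^(-4)` evaluated at its
#' fitted log-CPM (linear interpolation between smoother knots, constant
#' extrapolation beyond the observed range). Weights are floored at a small
#' positive value.
#'
#' @param log_cpm Matrix of log2-CPM values from [log_cpm()].
#' @param design Design matrix (samples x coefficients), full rank with at
#'   least 2 residual degrees of freedom.
#' @param span Lowess span. Default 0.5.
#' @param weight_floor Minimum weight. Default 1e-6.
#' @return Object of class `"precision_weights"`: list with `weights`
#'   (matrix, same dim as `log_cpm`), `trend` (`data.frame` of smoother
#'   knots: `mean_log_cpm`, `sqrt_sd`) and `span`.
#' @export
voom_weights <- function(log_cpm, design, span = 0.5, weight_floor = 1e-6) {
  y <- as.matrix(log_cpm)
  X <- as.matrix(design)
  n <- ncol(y)
  p <- qr(X)$rank
  assert_that(p == ncol(X), "design matrix is rank deficient")
  df_resid <- n - p
  assert_that(df_resid >= 2,
              "need at least 2 residual degrees of freedom for the trend")
  H <- X %*% solve(crossprod(X), t(X))
  fitted <- y %*% t(H)
  resid <- y - fitted
  sigma <- sqrt(rowSums(resid^2) / df_resid)
  if (all(sigma < 1e-12)) {
    stop("all genes have zero residual variance: degenerate input",
         call. = FALSE)
  }
  mean_lcpm <- rowMeans(y)
  # iter = 0: a single local fit keeps the smoother strictly local (no
  # global robustness reweighting), so a perturbation cannot move the
  # trend far from its own abundance region
  lo <- stats::lowess(mean_lcpm, sqrt(sigma), f = span, iter = 0, delta = 0)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  pred_sqrt_sd <- matrix(trend_fun(as.vector(fitted)), nrow = nrow(y))
  pred_sqrt_sd <- pmax(pred_sqrt_sd, 1e-4)
  w <- pred_sqrt_sd^(-4)
  w <- pmax(w, weight_floor)
  dimnames(w) <- dimnames(y)
  structure(list(weights = w,
                 trend = data.frame(mean_log_cpm = lo$x, sqrt_sd = lo$y),
                 span = span),
            class = "precision_weights")
}

#' @export
print.precision_weights <- function(x, ...) {
  cat("precision_weights:", nrow(x$weights), "genes x", ncol(x$weights),
      "samples; weight range [",
      format(min(x$weights), digits = 3), ",",
      format(max(x$weights), digits = 3), "]\n")
  invisible(x)
}

#' Full normalization of a count experiment
#'
#' Computes library sizes, TMM factors, effective sizes, log2-CPM and,
#' when gene lengths are available, log2-RPKM.
#'
#' @param experiment A [count_experiment()].
#' @param prior_count Pseudo-count for the log transforms. Default 0.5.
#' @param rpkm_use_effective Use TMM-effective library sizes for RPKM?
#'   Default `FALSE` (raw sizes).
#' @return Object of class `"normalization_result"`: list with `lib_sizes`,
#'   `tmm`, `effective_lib_sizes`, `log_cpm`, and `log_rpkm` (or `NULL`).
#' @export
normalize_experiment <- function(experiment, prior_count = 0.5,
                                 rpkm_use_effective = FALSE) {
  counts <- experiment$counts
  lib <- colSums(counts)
  f <- tmm_factors(counts)
  eff <- lib * f
  lcpm <- log_cpm(counts, eff, prior_count)
  lrpkm <- NULL
  if (!is.null(experiment$gene_lengths)) {
    sizes <- if (rpkm_use_effective) eff else lib
    lrpkm <- rpkm(counts, sizes, experiment$gene_lengths, prior_count,
                  log = TRUE)
  }
  structure(list(lib_sizes = lib, tmm = f, effective_lib_sizes = eff,
                 log_cpm = lcpm, log_rpkm = lrpkm),
            class = "normalization_result")
}
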