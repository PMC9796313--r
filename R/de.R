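#' Per-gene weighted least-squares fits
#'
#' Fits each gene's log2-CPM profile on the design matrix with
#' observation-level precision weights (ordinary least squares when
#' `weights` is `NULL` or constant).
#'
#' @param log_cpm Gene-by-sample matrix of log2-CPM values.
#' @param design Full-rank design matrix (samples x coefficients).
#' @param weights Optional matrix of positive observation weights, same
#'   dimensions as `log_cpm`.
#' @return Object of class `"gene_fits"`: list with `coefficients`
#'   (genes x coefficients), `cov_unscaled` (p x p x genes array of
#'   `(X'WX)^-1`), `sigma2` (residual variances), `df_residual`, `design`.
#' @export
fit_models <- function(log_cpm, design, weights = NULL) {
  y <- as.matrix(log_cpm)
  X <- as.matrix(design)
  n <- ncol(y)
  assert_that(nrow(X) == n, "design rows must match samples")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  df_resid <- n - p
  assert_that(df_resid >= 1, "no residual degrees of freedom")
  G <- nrow(y)
  if (is.null(weights)) {
    weights <- matrix(1, G, n)
  } else if (inherits(weights, "precision_weights")) {
    weights <- weights$weights
  }
  weights <- as.matrix(weights)
  assert_that(all(dim(weights) == dim(y)),
              "weights must match the expression matrix dimensions")
  assert_that(all(weights > 0), "weights must be positive")

  coef <- matrix(NA_real_, G, p, dimnames = list(rownames(y), colnames(X)))
  covu <- array(NA_real_, c(p, p, G))
  sigma2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    XtW <- t(X * w)
    A <- XtW %*% X
    Ainv <- solve(A)
    b <- Ainv %*% (XtW %*% y[g, ])
    r <- y[g, ] - as.vector(X %*% b)
    coef[g, ] <- b
    covu[, , g] <- Ainv
    sigma2[g] <- sum(w * r^2) / df_resid
  }
  structure(list(coefficients = coef, cov_unscaled = covu, sigma2 = sigma2,
                 df_residual = df_resid, design = X),
            class = "gene_fits")
}

#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, monotone and fast-converging;
#' used to solve the method-of-moments equation for the prior degrees of
#' freedom of the variance distribution.
#'
#' @param x Positive numeric vector.
#' @return `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  y <- rep(NA_real_, length(x))
  done <- !is.finite(x) | x <= 0
  y[!is.finite(x)] <- NaN
  y[x <= 0 & is.finite(x)] <- Inf
  big <- !done & x > 1e7
  y[big] <- 1 / sqrt(x[big])
  small <- !done & x < 1e-6
  y[small] <- 1 / x[small]
  todo <- !done & !big & !small
  if (any(todo)) {
    xx <- x[todo]
    yy <- 0.5 + 1 / xx
    for (i in 1:50) {
      tri <- trigamma(yy)
      dif <- tri * (1 - tri / xx) / psigamma(yy, deriv = 2)
      yy <- yy + dif
      if (max(-dif / yy) < 1e-8) break
    }
    y[todo] <- yy
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Pools each gene's residual variance s2 with a prior variance s02
#' estimated from all genes, assuming the gene variances follow a scaled
#' F / scaled inverse-chi-square model. The prior degrees of freedom d0 and
#' prior variance s02 are estimated by method of moments on log s2 (whose
#' mean and variance involve digamma/trigamma of the degrees of freedom);
#' the posterior variance is the df-weighted average
#' `(d0*s02 + d*s2) / (d0 + d)` and t-statistics gain `d0` degrees of
#' freedom. If the observed spread of log-variances is no larger than
#' expected under equal true variances, `d0 = Inf` and every posterior
#' variance equals `s02`.
#'
#' @param fits A [fit_models()] result.
#' @param d0_override Optional forced prior df: `0` bypasses moderation
#'   (ordinary t), `Inf` forces complete pooling.
#' @return Object of class `"moderated_fit"`: the fit plus `d0`, `s02`,
#'   `s2_post` and `df_total`.
#' @export
moderate <- function(fits, d0_override = NULL) {
  s2 <- fits$sigma2
  d <- fits$df_residual
  pos <- s2 > 0
  assert_that(sum(pos) >= 2,
              "need at least 2 genes with positive residual variance")
  if (is.null(d0_override)) {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no over-dispersion of the variances: infinite prior df, and the
      # prior variance is the geometric mean of the observed s2, so that
      # identical gene variances are returned unchanged
      d0 <- Inf
      s02 <- exp(mean(z))
    }
  } else {
    d0 <- d0_override
    assert_that(d0 >= 0, "d0 must be non-negative")
    s02 <- exp(mean(log(s2[pos])))
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  out <- fits
  out$d0 <- d0
  out$s02 <- s02
  out$s2_post <- s2_post
  out$df_total <- d0 + d
  class(out) <- c("moderated_fit", "gene_fits")
  out
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("moderated_fit:", nrow(x$coefficients), "genes; prior df d0 =",
      format(x$d0, digits = 4), "; prior variance s02 =",
      format(x$s02, digits = 4), "\n")
  invisible(x)
}

#' Moderated t-tests for a set of contrasts
#'
#' For each gene and contrast vector c: log2FC = c'beta, unscaled standard
#' error `u = sqrt(c' (X'WX)^-1 c)`, moderated
#' `t = log2FC / (u * sqrt(s2_post))` and two-sided p from the
#' t-distribution with `d0 + d` degrees of freedom. A Benjamini-Hochberg
#' adjusted column is included for reporting (the kinetic classifier
#' consumes the raw p-values).
#'
#' @param moderated_fit A [moderate()] result.
#' @param contrasts Matrix of contrast vectors (coefficients x contrasts),
#'   e.g. [sequential_contrasts()].
#' @return Named list of `data.frame`s, one per contrast, each with columns
#'   `gene_id`, `log2fc`, `t`, `p`, `bh_fdr`.
#' @export
test_contrasts <- function(moderated_fit, contrasts) {
  fit <- moderated_fit
  assert_that(!is.null(fit$s2_post), "run moderate() before test_contrasts()")
  C <- as.matrix(contrasts)
  p_coef <- ncol(fit$coefficients)
  assert_that(nrow(C) == p_coef,
              "contrast length must equal the number of design coefficients")
  G <- nrow(fit$coefficients)
  genes <- rownames(fit$coefficients)
  if (is.null(genes)) genes <- paste0("gene", seq_len(G))
  out <- vector("list", ncol(C))
  names(out) <- colnames(C)
  df <- fit$df_total
  for (k in seq_len(ncol(C))) {
    cv <- C[, k]
    lfc <- as.vector(fit$coefficients %*% cv)
    u2 <- vapply(seq_len(G),
                 function(g) as.numeric(t(cv) %*% fit$cov_unscaled[, , g] %*% cv),
                 numeric(1))
    assert_that(all(u2 > 0), "contrast outside the span of the design")
    tt <- lfc / sqrt(u2 * fit$s2_post)
    pp <- 2 * stats::pt(-abs(tt), df = df)
    pp <- pmin(pmax(pp, .Machine$double.xmin), 1)
    out[[k]] <- data.frame(gene_id = genes, log2fc = lfc, t = tt, p = pp,
                           bh_fdr = stats::p.adjust(pp, method = "BH"),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Differential expression over the two sequential time contrasts
#'
#' Normalization (TMM + log-CPM), precision weights, weighted fits,
#' variance moderation and the two contrasts 30 min vs 0 and 3 h vs 30 min
#' in one call.
#'
#' @param experiment A [count_experiment()].
#' @param span Lowess span for the mean-variance trend. Default 0.5.
#' @return List with `normalization`, `weights`, `fit` (moderated) and
#'   `contrasts` (list of two per-contrast tables).
#' @export
run_de <- function(experiment, span = 0.5) {
  norm <- normalize_experiment(experiment)
  X <- design_matrix(experiment$design)
  w <- voom_weights(norm$log_cpm, X, span = span)
  fit <- fit_models(norm$log_cpm, X, w)
  mfit <- moderate(fit)
  res <- test_contrasts(mfit, sequential_contrasts(X))
  list(normalization = norm, weights = w, fit = mfit, contrasts = res)
}
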