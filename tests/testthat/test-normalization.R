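test_that("low-count filter applies the CPM rule exactly", {
  counts <- rbind(g1 = c(0, 0, 0, 0, 0, 0),
                  g2 = c(100, 120, 90, 110, 100, 95),
                  g3 = c(1, 0, 0, 0, 0, 0),
                  g4 = c(5, 6, 4, 5, 6, 5),
                  g5 = c(0, 0, 2000, 0, 0, 0))
  colnames(counts) <- paste0("s", 1:6)
  ce <- toy_experiment(counts + matrix(rpois(30, 50), 5, 6) * 0)
  # brute-force evaluation of the rule
  lib <- colSums(ce$counts)
  cpm <- t(t(ce$counts) / lib * 1e6)
  for (min_cpm in c(0, 1, 1000)) {
    for (min_samples in c(1, 2)) {
      want <- rownames(cpm)[rowSums(cpm >= min_cpm) >= min_samples]
      suppressMessages(
        got <- filter_low_counts(ce, min_cpm, min_samples))
      expect_identical(rownames(got$counts), want)
    }
  }
  # min_cpm = 0 is the identity; an all-zero gene dies at 1 CPM / 1 sample
  suppressMessages({
    expect_identical(filter_low_counts(ce, 0, 0)$counts, ce$counts)
    expect_false("g1" %in% rownames(filter_low_counts(ce, 1, 1)$counts))
  })
})

test_that("TMM factors are 1 for identical or purely rescaled columns", {
  set.seed(3)
  base <- rnbinom(500, mu = 100, size = 10) + 1
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(tmm_factors(counts)), c(1, 1, 1), tolerance = 1e-12)
  # a pure library-size change leaves proportions, hence factors, unchanged
  counts2 <- cbind(s1 = base, s2 = 4 * base, s3 = base)
  expect_equal(unname(tmm_factors(counts2)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("TMM matches an independent trimming oracle on a skewed fixture", {
  # 8 genes, one highly expressed sample-specific gene in s2
  counts <- cbind(s1 = c(100, 200, 300, 400, 500, 600, 700, 80),
                  s2 = c(110, 190, 310, 390, 510, 590, 710, 50000))
  rownames(counts) <- paste0("g", 1:8)
  f <- tmm_factors(counts)
  # reference is s1 (upper quartile closest to mean); oracle factor for s2
  want <- oracle_tmm_pair(counts[, 2], counts[, 1])
  want_pair <- c(1, want) / exp(mean(log(c(1, want))))
  expect_equal(unname(f), want_pair, tolerance = 1e-10)

  # larger random fixture, all four pairwise-vs-reference factors
  set.seed(9)
  m <- matrix(rnbinom(400 * 4, mu = exp(runif(400, 2, 8)), size = 8) + 1,
              400, 4, dimnames = list(paste0("g", 1:400), paste0("s", 1:4)))
  m[1:30, 3] <- m[1:30, 3] * 15
  f <- tmm_factors(m)
  lib <- colSums(m)
  uq <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  raw <- vapply(1:4, function(j) {
    if (j == ref) 1 else oracle_tmm_pair(m[, j], m[, ref])
  }, numeric(1))
  expect_equal(unname(f), raw / exp(mean(log(raw))), tolerance = 1e-10)
})

test_that("TMM factors are invariant to rescaling one sample", {
  set.seed(21)
  m <- matrix(rnbinom(1000 * 3, mu = exp(runif(1000, 2, 7)), size = 10) + 1,
              1000, 3, dimnames = list(NULL, paste0("s", 1:3)))
  f1 <- tmm_factors(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 7  # integer scaling, no rounding error
  f2 <- tmm_factors(m2)
  # invariance is approximate: the binomial precision weights see the
  # absolute counts, so a pure rescaling shifts factors only marginally
  expect_equal(f1, f2, tolerance = 0.01)
  expect_equal(exp(mean(log(f1))), 1, tolerance = 1e-6)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-6)
})

test_that("TMM agrees with the established reference implementation", {
  set.seed(42)
  m <- matrix(rnbinom(2000 * 6, mu = exp(runif(2000, 1, 8)), size = 5),
              2000, 6, dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  m[1:50, 1] <- m[1:50, 1] * 20
  expect_equal(unname(tmm_factors(m)),
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-12)
})

test_that("log-CPM and RPKM match direct formula evaluation", {
  # forced arithmetic: count 0, effective size 1e6 - 1, prior 0.5 -> -1
  m <- matrix(0, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(as.numeric(log_cpm(m, 1e6 - 1, prior_count = 0.5)), -1)

  set.seed(5)
  counts <- matrix(rpois(60, 200), 10, 6,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  eff <- colSums(counts) * runif(6, 0.8, 1.2)
  got <- log_cpm(counts, eff, prior_count = 0.5)
  want <- log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
  expect_equal(got, want, tolerance = 1e-12)

  lengths <- setNames(sample(500:5000, 10), rownames(counts))
  lin <- rpkm(counts, colSums(counts), lengths, prior_count = 0.5,
              log = FALSE)
  want_lin <- sweep(sweep(counts + 0.5, 2, colSums(counts) / 1e6, "/"),
                    1, lengths / 1000, "/")
  expect_equal(lin, want_lin, tolerance = 1e-12)
  expect_equal(rpkm(counts, colSums(counts), lengths, log = TRUE),
               log2(want_lin), tolerance = 1e-12)

  # worked example: 1000 reads, 2 kb exon, 1e6 library -> 500 RPKM
  m1 <- matrix(1000, 1, 1, dimnames = list("gA", "s1"))
  expect_equal(as.numeric(rpkm(m1, 1e6, c(gA = 2000), prior_count = 0,
                               log = FALSE)), 500)
  expect_equal(as.numeric(rpkm(m1, 1e6, c(gA = 2000), prior_count = 0)),
               log2(500))
  # doubling the exon length halves linear RPKM
  expect_equal(as.numeric(rpkm(m1, 1e6, c(gA = 4000), prior_count = 0,
                               log = FALSE)), 250)
  # missing length propagates as NA with a warning
  m2 <- rbind(m1, gB = 10)
  expect_warning(r2 <- rpkm(m2, 1e6, c(gA = 2000), log = FALSE),
                 "without length")
  expect_true(all(is.na(r2["gB", ])))
})

test_that("precision weights are flat for homoscedastic data", {
  set.seed(31)
  X <- design_matrix(data.frame(sample_id = paste0("s", 1:9),
                                time = rep(c("0", "0.5h", "3h"), each = 3),
                                replicate = rep(1:3, 3)))
  y <- matrix(rnorm(2000 * 9, mean = rep(runif(2000, 2, 10), 9), sd = 0.5),
              2000, 9, dimnames = list(paste0("g", 1:2000), paste0("s", 1:9)))
  w <- voom_weights(y, X)
  gene_w <- rowMeans(w$weights)
  expect_lt(sd(gene_w) / mean(gene_w), 0.15)  # near-constant weights
})

test_that("precision weights increase with abundance on count-like data", {
  set.seed(32)
  sim <- simulate_counts(simulation_config(n_genes = 1500, seed = 17))
  lcpm <- log_cpm(sim$experiment$counts)
  X <- design_matrix(sim$experiment$design)
  w <- voom_weights(lcpm, X)
  rho <- cor(rowMeans(lcpm), rowMeans(w$weights), method = "spearman")
  expect_gt(rho, 0)
})

test_that("perturbing one observation only moves nearby weights", {
  set.seed(33)
  X <- design_matrix(data.frame(sample_id = paste0("s", 1:9),
                                time = rep(c("0", "0.5h", "3h"), each = 3),
                                replicate = rep(1:3, 3)))
  mu <- seq(0, 12, length.out = 300)
  y <- matrix(rnorm(300 * 9, mean = rep(mu, 9), sd = 0.4), 300, 9)
  w1 <- voom_weights(y, X)
  y2 <- y
  y2[1, 1] <- y2[1, 1] + 3  # perturb a low-abundance gene
  w2 <- voom_weights(y2, X)
  far <- which(mu > 8)  # far from the perturbed abundance region
  expect_lt(max(abs(w2$weights[far, ] - w1$weights[far, ]) /
                  w1$weights[far, ]), 1e-6)
})

test_that("degenerate zero-variance input is rejected", {
  X <- design_matrix(data.frame(sample_id = paste0("s", 1:6),
                                time = rep(c("0", "0.5h", "3h"), each = 2),
                                replicate = rep(1:2, 3)))
  y <- matrix(rep(1:5, each = 6), 5, 6, byrow = TRUE)
  expect_error(voom_weights(y, X), "zero residual variance")
})
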