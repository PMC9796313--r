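test_that("configuration invariants are enforced", {
  expect_error(simulation_config(class_proportions = c(A1 = 1)), "nine")
  bad <- default_class_proportions()
  bad["none"] <- bad["none"] + 0.1
  expect_error(simulation_config(class_proportions = bad), "sum to 1")
  expect_error(simulation_config(effect_size = -1), "effect_size")
  expect_error(simulation_config(dispersion = -0.1), "dispersion")
  expect_equal(sum(default_class_proportions()), 1, tolerance = 1e-12)
})

test_that("simulation is seed-reproducible and structurally sound", {
  cfg <- simulation_config(n_genes = 300, seed = 12)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$experiment$counts, s2$experiment$counts)
  expect_identical(s1$truth, s2$truth)
  counts <- s1$experiment$counts
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  expect_identical(dim(counts), c(300L, 9L))
  # realized column sums stay within 25% of the drawn targets
  expect_true(all(abs(colSums(counts) / s1$target_lib_sizes - 1) < 0.25))
  # planted effects are consistent with the class sign pattern
  tab <- kinetic_class_table()
  sgn <- c(up = 1, down = -1, ns = 0)
  i <- match(s1$truth$class, tab$class)
  expect_equal(sign(s1$truth$effect1), unname(sgn[tab$call1[i]]))
  expect_equal(sign(s1$truth$effect2), unname(sgn[tab$call2[i]]))
})

test_that("simulated counts match negative-binomial moments", {
  # one gene observed many times: mean m, variance m + phi m^2
  cfg <- simulation_config(n_genes = 10000, n_replicates = 1,
                           class_proportions = c(
                             A1 = 0, A2 = 0, B1 = 0, B2 = 0, C1 = 0,
                             C2 = 0, D1 = 0, D2 = 0, none = 1),
                           baseline_log2_mean_range = c(7, 7),
                           dispersion = 0.1,
                           library_size_range = c(10000 * 2^7, 10000 * 2^7),
                           seed = 2)
  s <- simulate_counts(cfg)
  x <- s$experiment$counts[, 1]  # 10,000 iid NB(m = 128, phi = 0.1) draws
  m <- 2^7
  v <- m + 0.1 * m^2
  expect_lt(abs(mean(x) - m) / m, 4 * sqrt(v / 10000) / m)
  # variance within Monte-Carlo error (kurtosis-based SE, generous factor)
  expect_lt(abs(var(x) - v) / v, 0.15)
})

test_that("zero dispersion degenerates to Poisson-like variance", {
  cfg <- simulation_config(n_genes = 10000, n_replicates = 1,
                           class_proportions = c(
                             A1 = 0, A2 = 0, B1 = 0, B2 = 0, C1 = 0,
                             C2 = 0, D1 = 0, D2 = 0, none = 1),
                           baseline_log2_mean_range = c(6, 6),
                           dispersion = 0,
                           library_size_range = c(10000 * 2^6, 10000 * 2^6),
                           seed = 3)
  x <- simulate_counts(cfg)$experiment$counts[, 1]
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
})

test_that("null simulations keep the classifier silent", {
  rates <- vapply(1:3, function(seed) {
    cfg <- simulation_config(n_genes = 800, effect_size = 0, seed = seed)
    sim <- simulate_counts(cfg)
    expect_true(all(sim$truth$class == "none"))  # zero effect plants nothing
    de <- suppressMessages(run_de(sim$experiment))
    calls <- classify_genes(de$contrasts)
    mean(calls$class != "none")
  }, numeric(1))
  expect_true(all(rates <= 0.05))
})

test_that("class recovery improves with planted effect size", {
  acc <- vapply(c(0.5, 1.5, 3), function(es) {
    cfg <- simulation_config(n_genes = 600, effect_size = es,
                             baseline_log2_mean_range = c(7, 12),
                             seed = 101)
    sim <- simulate_counts(cfg)
    de <- suppressMessages(run_de(sim$experiment))
    calls <- classify_genes(de$contrasts)
    truth <- sim$truth$class[match(calls$gene_id, sim$truth$gene_id)]
    nn <- truth != "none"
    mean(calls$class[nn] == truth[nn])
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gte(acc[3], 0.9)
})

test_that("simulated ontologies are rooted DAGs with true-path annotations", {
  for (seed in 1:3) {
    onto <- simulate_ontology(n_terms = 30, genes = paste0("g", 1:20),
                              seed = seed)
    g <- onto$graph
    expect_identical(length(g$roots), 1L)
    expect_true(igraph::is_dag(g$graph))
    non_root <- setdiff(g$terms$id, g$roots)
    expect_true(all(non_root %in% g$edges$child))  # every term has a parent
    # annotations closed under ancestry
    for (gene in sample(names(onto$annotation), 5)) {
      ts <- onto$annotation[[gene]]
      anc <- unique(unlist(g$ancestors[ts]))
      expect_true(all(anc %in% ts))
    }
  }
  # determinism and the 2-term degenerate case
  o1 <- simulate_ontology(n_terms = 12, genes = "g1", seed = 9)
  o2 <- simulate_ontology(n_terms = 12, genes = "g1", seed = 9)
  expect_identical(o1$graph$edges, o2$graph$edges)
  tiny <- simulate_ontology(n_terms = 2, genes = "g1",
                            annotation_density = 1, seed = 1)
  expect_identical(nrow(tiny$graph$edges), 1L)
  expect_setequal(tiny$annotation$g1, tiny$graph$terms$id)
})

test_that("simulated grids have the plate layout and gradient behaviour", {
  g <- simulate_grid(seed = 1)
  expect_identical(g$n_rows, 4L)
  expect_identical(g$n_cols, 9L)
  # 36 blocks per analyte
  expect_identical(nrow(g$blocks[g$blocks$analyte == "ORS", ]), 36L)
  # zero noise: pigment analyte and absorbance are exact monotone images
  g0 <- simulate_grid(noise_sd = 0, seed = 2)
  expect_equal(spearman_association(g0, "ORS")$rho, 1)
  # heavy noise attenuates the association toward zero on a seed panel
  rho_mod <- vapply(1:50, function(s)
    spearman_association(simulate_grid(noise_sd = 0.2, seed = s),
                         "ORS")$rho, numeric(1))
  rho_big <- vapply(1:50, function(s)
    spearman_association(simulate_grid(noise_sd = 5, seed = s),
                         "ORS")$rho, numeric(1))
  expect_lt(mean(abs(rho_big)), mean(abs(rho_mod)))
  expect_lt(mean(abs(rho_big)), 0.3)
})
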