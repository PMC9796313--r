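#' Default kinetic-class proportions for simulated experiments
#'
#' Relative class frequencies modelled on a real macrolide-treatment time
#' course in *Aspergillus nidulans*, where roughly 17.5% of ~10,000 genes
#' responded, dominated by the delayed classes: A1 1.25%, A2 2.36%,
#' B1 0.22%, B2 0.16%, C1 6.38%, C2 5.73%, D1 0.54%, D2 0.90%, none the
#' remainder.
#'
#' @return Named numeric vector over the nine class labels, summing to 1.
#' @export
default_class_proportions <- function() {
  p <- c(A1 = 0.0125, A2 = 0.0236, B1 = 0.0022, B2 = 0.0016,
         C1 = 0.0638, C2 = 0.0573, D1 = 0.0054, D2 = 0.0090)
  c(p, none = 1 - sum(p))
}

#' Configuration for the count simulator
#'
#' Defines the simulated study: three conditions (untreated, 30 min and
#' 3 h after treatment), negative-binomial counts and per-gene planted
#' kinetic classes realized as log2 effects on the two sequential steps.
#'
#' @param n_genes Number of genes. Default 5000.
#' @param n_replicates Replicates per condition. Default 3.
#' @param time_points The three ordered condition labels.
#' @param class_proportions Named vector over the nine class labels summing
#'   to 1. Default [default_class_proportions()].
#' @param effect_size Planted |log2 fold change| per regulated step
#'   (log2 units). Default 2, comfortably above the >1 call threshold.
#' @param baseline_log2_mean_range Interval for per-gene baseline log2 mean
#'   abundance. Default `c(2, 12)`.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `m + phi * m^2`); 0 gives Poisson counts. Default 0.05.
#' @param library_size_range Interval of target per-sample column sums.
#'   Default `c(8e6, 12e6)`.
#' @param seed Master integer seed. Default 1.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 5000,
                              n_replicates = 3,
                              time_points = TIME_POINTS,
                              class_proportions = default_class_proportions(),
                              effect_size = 2,
                              baseline_log2_mean_range = c(2, 12),
                              dispersion = 0.05,
                              library_size_range = c(8e6, 12e6),
                              seed = 1) {
  assert_that(n_genes >= 1 && n_genes == round(n_genes),
              "n_genes must be a positive integer")
  assert_that(n_replicates >= 1 && n_replicates == round(n_replicates),
              "n_replicates must be a positive integer")
  assert_that(length(time_points) == 3, "exactly three time points required")
  labels <- kinetic_class_table()$class
  assert_that(all(names(class_proportions) %in% labels) &&
                all(labels %in% names(class_proportions)),
              "class_proportions must cover exactly the nine class labels")
  assert_that(all(class_proportions >= 0),
              "class proportions must be non-negative")
  assert_that(abs(sum(class_proportions) - 1) <= 1e-9,
              "class proportions must sum to 1")
  assert_that(effect_size >= 0, "effect_size must be >= 0")
  assert_that(dispersion >= 0, "dispersion must be >= 0")
  assert_that(length(baseline_log2_mean_range) == 2 &&
                diff(baseline_log2_mean_range) >= 0,
              "baseline_log2_mean_range must be an interval")
  assert_that(length(library_size_range) == 2 &&
                all(library_size_range > 0) &&
                diff(library_size_range) >= 0,
              "library_size_range must be a positive interval")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 time_points = as.character(time_points),
                 class_proportions = class_proportions[labels],
                 effect_size = effect_size,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# integer class counts by largest remainder, summing exactly to n
apportion_classes <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

# per-class signed step pattern in log2 units
class_effects <- function(classes, effect_size) {
  tab <- kinetic_class_table()
  sgn <- c(up = 1, down = -1, ns = 0)
  i <- match(classes, tab$class)
  cbind(e1 = sgn[tab$call1[i]] * effect_size,
        e2 = sgn[tab$call2[i]] * effect_size)
}

#' Simulate a treatment time-course count experiment with planted classes
#'
#' Each gene gets a kinetic class (drawn per `class_proportions`), a
#' baseline mean `2^U(range)`, and condition means following the planted
#' effects cumulatively: baseline, baseline * 2^e1, baseline * 2^(e1+e2).
#' Per-sample means are scaled so each expected column sum equals a target
#' library size drawn from `library_size_range`; this common per-condition
#' offset is the library/composition effect that TMM normalization is
#' designed to absorb. Counts are negative-binomial with dispersion phi
#' (Poisson when phi = 0).
#'
#' @param config A [simulation_config()].
#' @return List with `experiment` (a [count_experiment()]) and `truth`
#'   (`data.frame`: `gene_id`, `class`, `effect1`, `effect2`).
#' @export
simulate_counts <- function(config) {
  assert_that(inherits(config, "simulation_config"),
              "config must be a simulation_config")
  set.seed(derive_seed(config$seed, "counts"))
  G <- config$n_genes
  R <- config$n_replicates
  genes <- sprintf("g%05d", seq_len(G))

  counts_per_class <- apportion_classes(config$class_proportions, G)
  classes <- sample(rep(names(counts_per_class), counts_per_class))
  eff <- class_effects(classes, config$effect_size)
  # the stored truth is the class realized by the effect sign pattern, so a
  # zero effect size plants "none" everywhere by construction
  sgn_call <- function(e) c("down", "ns", "up")[sign(e) + 2]
  classes <- classify_kinetics(sgn_call(eff[, "e1"]), sgn_call(eff[, "e2"]))

  rng <- config$baseline_log2_mean_range
  baseline <- 2^stats::runif(G, rng[1], rng[2])
  # cumulative planted effects: per-condition expected mean profile
  cum <- cbind(0, eff[, "e1"], eff[, "e1"] + eff[, "e2"])
  mu_cond <- baseline * 2^cum  # G x 3

  times <- rep(config$time_points, each = R)
  samples <- paste0("s_", rep(config$time_points, each = R), "_r",
                    rep(seq_len(R), times = 3))
  samples <- gsub("[^A-Za-z0-9_]", "", samples)
  targets <- stats::runif(length(samples),
                          config$library_size_range[1],
                          config$library_size_range[2])
  cond_idx <- rep(seq_along(config$time_points), each = R)
  cond_total <- colSums(mu_cond)

  counts <- matrix(0, G, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mu <- mu_cond[, cond_idx[j]] * (targets[j] / cond_total[cond_idx[j]])
    counts[, j] <- if (config$dispersion == 0) {
      stats::rpois(G, mu)
    } else {
      stats::rnbinom(G, mu = mu, size = 1 / config$dispersion)
    }
  }
  design <- data.frame(sample_id = samples, time = times,
                       replicate = rep(seq_len(R), times = 3),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes, class = classes,
                      effect1 = unname(eff[, "e1"]),
                      effect2 = unname(eff[, "e2"]),
                      stringsAsFactors = FALSE)
  list(experiment = count_experiment(counts, design),
       truth = truth,
       target_lib_sizes = stats::setNames(targets, samples))
}

#' Simulate a small is_a ontology with gene annotations
#'
#' Builds a rooted directed acyclic graph: term 1 is the root; every later
#' term attaches to one earlier term with spare child capacity
#' (`max_children`) and, with probability 0.2, to a second one, so the
#' graph is a DAG rather than a tree. Each gene is directly annotated to
#' each term independently with probability `annotation_density`, and the
#' returned annotation is closed under ancestry (true-path rule); genes
#' left unannotated get the root.
#'
#' @param n_terms Number of terms (>= 2).
#' @param max_children Maximum direct children per term. Default 5.
#' @param annotation_density Per-(gene, term) direct annotation
#'   probability. Default 0.1.
#' @param genes Character vector of gene ids to annotate.
#' @param seed Integer seed.
#' @return List with `graph` (an [ontology_graph()]) and `annotation`
#'   (named list gene -> ancestor-closed term ids).
#' @export
simulate_ontology <- function(n_terms, max_children = 5,
                              annotation_density = 0.1,
                              genes = sprintf("g%05d", 1:50),
                              seed = 1) {
  assert_that(n_terms >= 2, "need at least 2 terms")
  set.seed(derive_seed(seed, "ontology"))
  ids <- sprintf("T:%07d", seq_len(n_terms))
  child_count <- integer(n_terms)
  edges <- list()
  for (i in 2:n_terms) {
    open <- which(child_count[seq_len(i - 1)] < max_children)
    if (length(open) == 0) open <- seq_len(i - 1)
    p1 <- open[sample.int(length(open), 1)]
    child_count[p1] <- child_count[p1] + 1
    parents <- p1
    if (i > 2 && stats::runif(1) < 0.2) {
      others <- setdiff(seq_len(i - 1), p1)
      p2 <- others[sample.int(length(others), 1)]
      child_count[p2] <- child_count[p2] + 1
      parents <- c(parents, p2)
    }
    edges[[length(edges) + 1]] <- data.frame(child = ids[i],
                                             parent = ids[parents])
  }
  graph <- ontology_graph(
    terms = data.frame(id = ids, name = paste("term", seq_len(n_terms))),
    edges = do.call(rbind, edges))
  direct <- lapply(genes, function(g) {
    hit <- ids[stats::runif(n_terms) < annotation_density]
    if (length(hit) == 0) hit <- ids[1]
    hit
  })
  names(direct) <- genes
  list(graph = graph, annotation = propagate_annotations(direct, graph))
}

#' Simulate a confrontation-assay gradient grid
#'
#' Emulates a plate on which metabolite production rises toward the
#' confronting colony: a latent linear gradient along the stated axis
#' drives every analyte, each observed as gradient signal plus Gaussian
#' noise (floored at 0), and the absorbance channel is a strictly
#' increasing affine function of the designated pigment analyte's latent
#' gradient plus the same relative noise. With `noise_sd = 0` the pigment
#' analyte and the absorbance are exact monotone images of each other.
#'
#' @param n_rows,n_cols Grid dimensions. Defaults 4 x 9, the plate layout
#'   of a 15-cm confrontation assay cut into 1-cm blocks.
#' @param analytes Analyte names; the first is the pigment driving the
#'   absorbance channel. Default `c("ORS", "LEC")`.
#' @param gradient_direction `"col"` (default) or `"row"`: axis along
#'   which concentrations increase.
#' @param noise_sd Noise standard deviation relative to the gradient span.
#'   Default 0.2.
#' @param seed Integer seed.
#' @return A [spatial_grid()] containing the analytes plus
#'   `"absorbance_400nm"`.
#' @export
simulate_grid <- function(n_rows = 4, n_cols = 9,
                          analytes = c("ORS", "LEC"),
                          gradient_direction = c("col", "row"),
                          noise_sd = 0.2, seed = 1) {
  assert_that(n_rows >= 1 && n_cols >= 1, "grid dimensions must be >= 1")
  assert_that(length(analytes) >= 1, "need at least one analyte")
  gradient_direction <- match.arg(gradient_direction)
  set.seed(derive_seed(seed, "grid"))
  pos <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  axis <- if (gradient_direction == "col") pos$col else pos$row
  span <- max(axis) - min(axis)
  latent <- if (span == 0) rep(0.5, nrow(pos)) else
    (axis - min(axis)) / span  # 0..1 toward the confronting colony
  blocks <- list()
  for (a in analytes) {
    scale_a <- stats::runif(1, 50, 200)  # instrument-units full scale
    v <- latent * scale_a +
      stats::rnorm(nrow(pos), 0, noise_sd * scale_a)
    blocks[[a]] <- data.frame(row = pos$row, col = pos$col, analyte = a,
                              value = pmax(v, 0))
  }
  abs_scale <- 2  # AU full scale at 400 nm
  v <- 0.05 + latent * abs_scale +
    stats::rnorm(nrow(pos), 0, noise_sd * abs_scale)
  blocks[["absorbance_400nm"]] <- data.frame(
    row = pos$row, col = pos$col, analyte = "absorbance_400nm",
    value = pmax(v, 0))
  spatial_grid(do.call(rbind, blocks))
}
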