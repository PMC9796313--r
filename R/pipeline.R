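#' Pipeline configuration
#'
#' Collects input paths (or simulation settings), thresholds and the master
#' seed for an end-to-end run. When `counts_path` is `NULL` the run is
#' synthetic: inputs are generated by the simulators under the master seed.
#'
#' @param out_dir Output directory.
#' @param counts_path,design_path Count matrix and design TSVs (`NULL` for
#'   a synthetic run).
#' @param lengths_path Optional gene-lengths TSV.
#' @param gff3_path Optional GFF3 (exon-union lengths computed when
#'   `lengths_path` is absent).
#' @param obo_path,annotation_path Ontology and gene annotation inputs
#'   (simulated when absent in a synthetic run).
#' @param bgc_path BGC membership TSV (optional).
#' @param grid_path Spatial grid TSV (simulated when absent in a synthetic
#'   run).
#' @param lfc_min,p_max Regulation-call thresholds. Defaults 1.0, 0.01.
#' @param min_cpm,min_samples Low-count filter thresholds. Defaults 1, 2.
#' @param min_term_size,cut_distance Enrichment/clustering settings.
#' @param sim Simulation settings: a [simulation_config()] (its seed is
#'   overridden by `seed`).
#' @param seed Master seed. Default 1.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            counts_path = NULL, design_path = NULL,
                            lengths_path = NULL, gff3_path = NULL,
                            obo_path = NULL, annotation_path = NULL,
                            bgc_path = NULL, grid_path = NULL,
                            lfc_min = 1.0, p_max = 0.01,
                            min_cpm = 1, min_samples = 2,
                            min_term_size = 3, cut_distance = 2,
                            sim = simulation_config(),
                            seed = 1) {
  assert_that(lfc_min > 0 && p_max > 0 && min_term_size > 0 &&
                cut_distance > 0, "thresholds must be positive")
  for (p in c(counts_path, design_path, lengths_path, gff3_path, obo_path,
              annotation_path, bgc_path, grid_path)) {
    assert_that(file.exists(p), paste("input file not found:", p))
  }
  structure(list(out_dir = out_dir, counts_path = counts_path,
                 design_path = design_path, lengths_path = lengths_path,
                 gff3_path = gff3_path, obo_path = obo_path,
                 annotation_path = annotation_path, bgc_path = bgc_path,
                 grid_path = grid_path, lfc_min = lfc_min, p_max = p_max,
                 min_cpm = min_cpm, min_samples = min_samples,
                 min_term_size = min_term_size, cut_distance = cut_distance,
                 sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an optional
#' `sim:` block mirrors [simulation_config()].
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  sim_args <- y$sim
  y$sim <- NULL
  sim <- do.call(simulation_config, if (is.null(sim_args)) list()
                 else sim_args)
  do.call(pipeline_config, c(y, list(sim = sim)))
}

#' Run the full pipeline
#'
#' Stages: input acquisition (files or simulators), low-count filtering,
#' TMM + log-CPM (+ RPKM when lengths exist), precision-weighted moderated
#' differential testing of the two sequential contrasts, kinetic
#' classification, per-class ontology enrichment with term clustering, BGC
#' summaries (when a membership table is given) and spatial grid
#' association. All tables are written under `out_dir` together with a
#' `manifest.yaml` recording package version, parameters, seed and input
#' checksums. Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  synthetic <- is.null(config$counts_path)
  truth <- NULL

  if (synthetic) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- simulate_counts(sim_cfg)
    experiment <- sim$experiment
    truth <- sim$truth
  } else {
    lengths_path <- config$lengths_path
    experiment <- read_counts(config$counts_path, config$design_path,
                              lengths_path)
    if (is.null(lengths_path) && !is.null(config$gff3_path)) {
      experiment$gene_lengths <- gene_lengths_from_gff3(config$gff3_path)
    }
  }

  filtered <- filter_low_counts(experiment, config$min_cpm,
                                config$min_samples)
  de <- run_de(filtered)
  calls <- classify_genes(de$contrasts, config$lfc_min, config$p_max)
  class_summary <- summarize_classes(calls$class, calls$gene_id)

  if (!is.null(config$obo_path)) {
    graph <- read_obo(config$obo_path)
    annotation <- read_annotation(config$annotation_path)
  } else if (synthetic) {
    onto <- simulate_ontology(n_terms = 40,
                              genes = rownames(filtered$counts),
                              seed = config$seed)
    graph <- onto$graph
    annotation <- onto$annotation
  } else {
    graph <- NULL
  }
  enrichment <- if (!is.null(graph)) {
    enrich_classes(class_summary, annotation, graph,
                   min_term_size = config$min_term_size,
                   cut_distance = config$cut_distance)
  }

  bgc <- if (!is.null(config$bgc_path)) {
    summarize_bgc(calls, read_bgc_membership(config$bgc_path))
  }

  grid <- if (!is.null(config$grid_path)) {
    read_grid(config$grid_path)
  } else if (synthetic) {
    simulate_grid(seed = config$seed)
  }
  spatial <- if (!is.null(grid)) {
    metabolites <- setdiff(grid$analytes, "absorbance_400nm")
    do.call(rbind, lapply(metabolites, function(a)
      spearman_association(grid, a, n_perm = 1000, seed = config$seed)))
  }

  tables <- list(
    tmm_factors = data.frame(sample_id = names(de$normalization$tmm),
                             lib_size = unname(de$normalization$lib_sizes),
                             tmm = unname(de$normalization$tmm)),
    log_cpm = de$normalization$log_cpm,
    de_contrast1 = de$contrasts[[1]],
    de_contrast2 = de$contrasts[[2]],
    kinetic_calls = calls,
    class_summary = class_summary)
  if (!is.null(de$normalization$log_rpkm)) {
    tables$log_rpkm <- de$normalization$log_rpkm
  }
  if (!is.null(truth)) tables$truth <- truth
  if (!is.null(bgc)) tables$bgc_summary <- bgc
  if (!is.null(spatial)) tables$spatial_association <- spatial
  if (!is.null(enrichment)) {
    for (cl in names(enrichment)) {
      tables[[paste0("enrichment_", cl)]] <- enrichment[[cl]]$enrichment
      if (!is.null(enrichment[[cl]]$clusters)) {
        tables[[paste0("term_clusters_", cl)]] <- enrichment[[cl]]$clusters
      }
    }
  }
  write_results(tables, config$out_dir)
  write_gene_sets(attr(class_summary, "gene_sets"),
                  file.path(config$out_dir, "class_gene_sets.gmt"))

  inputs <- Filter(Negate(is.null),
                   config[c("counts_path", "design_path", "lengths_path",
                            "gff3_path", "obo_path", "annotation_path",
                            "bgc_path", "grid_path")])
  manifest <- list(
    package = "tcKinetics",
    version = as.character(utils::packageVersion("tcKinetics")),
    seed = config$seed,
    synthetic = synthetic,
    parameters = config[c("lfc_min", "p_max", "min_cpm", "min_samples",
                          "min_term_size", "cut_distance")],
    input_checksums = if (length(inputs) > 0)
      as.list(tools::md5sum(unlist(inputs))) else list())
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(experiment = experiment, filtered = filtered, de = de,
                 calls = calls, class_summary = class_summary,
                 enrichment = enrichment, bgc = bgc, grid = grid,
                 spatial = spatial, truth = truth, manifest = manifest))
}
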