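#' Read a count matrix and its design table
#'
#' The counts TSV has a header line `gene_id` followed by sample ids, one
#' gene per row; the design TSV has columns `sample_id`, `time`,
#' `replicate`. Validation (integer non-negative counts, matching samples,
#' unique gene ids) happens in [count_experiment()].
#'
#' @param counts_path Path to the counts TSV.
#' @param design_path Path to the design TSV.
#' @param lengths_path Optional path to a gene-lengths TSV (`gene_id`,
#'   `length`).
#' @return A [count_experiment()].
#' @export
read_counts <- function(counts_path, design_path, lengths_path = NULL) {
  tab <- read_tsv(counts_path)
  assert_that(names(tab)[1] == "gene_id",
              "counts file must start with a 'gene_id' column")
  genes <- as.character(tab$gene_id)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count entries found", call. = FALSE)
  rownames(m) <- genes
  design <- read_tsv(design_path)
  lengths <- if (!is.null(lengths_path)) read_gene_lengths(lengths_path)
  count_experiment(m, design, lengths)
}

#' Read a gene-length table
#'
#' @param path TSV with columns `gene_id` and `length` (bp).
#' @return Named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  tab <- read_tsv(path)
  assert_that(all(c("gene_id", "length") %in% names(tab)),
              "lengths file needs columns gene_id, length")
  stats::setNames(as.numeric(tab$length), as.character(tab$gene_id))
}

#' Read named gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated.
#'
#' @param gmt_path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  assert_that(!anyDuplicated(names(sets)), "duplicate gene set names in GMT")
  sets
}

#' Write named gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @export
write_gene_sets <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal OBO ontology
#'
#' Supports the `[Term]` stanzas with `id`, `name`, `is_a` and
#' `is_obsolete` tags (trailing `! comment` text on is_a lines is
#' stripped); obsolete terms are dropped. Cyclic is_a relations are a
#' structural error.
#'
#' @param obo_path Path to the OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(obo_path) {
  lines <- readLines(obo_path, warn = FALSE)
  ids <- character(0); names_ <- character(0)
  edges_child <- character(0); edges_parent <- character(0)
  cur_id <- NA_character_; cur_name <- NA_character_
  cur_parents <- character(0); cur_obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id) && !cur_obsolete) {
      ids <<- c(ids, cur_id)
      names_ <<- c(names_, if (is.na(cur_name)) cur_id else cur_name)
      if (length(cur_parents) > 0) {
        edges_child <<- c(edges_child, rep(cur_id, length(cur_parents)))
        edges_parent <<- c(edges_parent, cur_parents)
      }
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur_id <- NA_character_; cur_name <- NA_character_
      cur_parents <- character(0); cur_obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur_name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur_parents <- c(cur_parents, p)
    } else if (in_term && grepl("^is_obsolete:", ln)) {
      cur_obsolete <- grepl("true", ln)
    }
  }
  flush()
  # is_a links to terms dropped as obsolete (or undeclared) are skipped
  keep <- edges_parent %in% ids & edges_child %in% ids
  ontology_graph(
    terms = data.frame(id = ids, name = names_, stringsAsFactors = FALSE),
    edges = data.frame(child = edges_child[keep],
                       parent = edges_parent[keep],
                       stringsAsFactors = FALSE))
}

#' Write a minimal OBO ontology
#'
#' @param graph An [ontology_graph()].
#' @param path Output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i])), con)
    parents <- graph$edges$parent[graph$edges$child == id]
    for (p in parents) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id` and `term_id` (GAF-like
#'   two-column subset).
#' @return Named list gene id -> character vector of term ids.
#' @export
read_annotation <- function(path) {
  tab <- read_tsv(path)
  assert_that(all(c("gene_id", "term_id") %in% names(tab)),
              "annotation needs columns gene_id, term_id")
  lapply(split(as.character(tab$term_id), as.character(tab$gene_id)), unique)
}

#' Write a gene-to-term annotation table
#'
#' @param annotation Named list gene id -> term ids.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(gene_id = rep(names(annotation), lengths(annotation)),
                   term_id = unlist(annotation, use.names = FALSE))
  write_tsv(df, path)
}

#' Read a spatial grid table
#'
#' @param tsv_path TSV with columns `row`, `col`, `analyte`, `value`.
#' @return A [spatial_grid()].
#' @export
read_grid <- function(tsv_path) {
  spatial_grid(read_tsv(tsv_path))
}

#' Write a spatial grid table
#'
#' @param grid A [spatial_grid()].
#' @param path Output path.
#' @export
write_grid <- function(grid, path) {
  write_tsv(grid$blocks, path)
}

#' Read a BGC membership table
#'
#' @param path TSV with columns `cluster_id` and `gene_id`.
#' @return The validated `data.frame`.
#' @export
read_bgc_membership <- function(path) {
  tab <- read_tsv(path)
  assert_that(all(c("cluster_id", "gene_id") %in% names(tab)),
              "membership needs columns cluster_id, gene_id")
  tab
}

#' Write a count experiment to counts/design (and optional lengths) TSVs
#'
#' @param experiment A [count_experiment()].
#' @param counts_path,design_path,lengths_path Output paths
#'   (`lengths_path` only used when lengths are present).
#' @export
write_counts <- function(experiment, counts_path, design_path,
                         lengths_path = NULL) {
  df <- data.frame(gene_id = rownames(experiment$counts),
                   experiment$counts, check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(experiment$design, design_path)
  if (!is.null(lengths_path) && !is.null(experiment$gene_lengths)) {
    write_tsv(data.frame(gene_id = names(experiment$gene_lengths),
                         length = unname(experiment$gene_lengths)),
              lengths_path)
  }
  invisible(counts_path)
}

#' Write a named list of result tables as TSV files
#'
#' @param tables Named list of `data.frame`s (or matrices, written with a
#'   leading id column from their rownames).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(id = rownames(x), x, check.names = FALSE)
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
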