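#' @keywords internal
"_PACKAGE"

# Time-point labels used throughout: untreated baseline, 30 min and 3 h after
# treatment. Stored as ordered factor levels.
TIME_POINTS <- c("0", "0.5h", "3h")

# Names of the two sequential contrast windows (later minus earlier time).
CONTRAST_NAMES <- c("30min_vs_0", "3h_vs_30min")

#' Derive a stage-specific random seed from a master seed
#'
#' Every stochastic stage (count simulation, ontology simulation, grid
#' simulation, permutation tests) draws its seed deterministically from one
#' master seed, so a single integer reproduces an entire pipeline run while
#' stages stay independently re-runnable.
#'
#' @param seed Master integer seed.
#' @param stage Stage label, one of `"counts"`, `"ontology"`, `"grid"`,
#'   `"perm"`, `"noise"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(counts = 101, ontology = 211, grid = 307, perm = 401,
               noise = 503)
  if (!stage %in% names(offsets)) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  seed <- as.numeric(seed)
  if (!is.finite(seed)) stop("seed must be a finite number", call. = FALSE)
  as.integer((abs(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# stopifnot with a readable message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# tab-separated writer used for every output table: UTF-8, "." decimal,
# no quoting, no scientific-notation forcing
write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
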