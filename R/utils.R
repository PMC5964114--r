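#' @import methods
#' @importFrom stats setNames
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# random-number stream. All internal stochastic steps (k-means restarts,
# simulators) run through this so results are reproducible regardless of what
# the session did before.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed so independent
# generators never share a stream. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  (as.double(seed) * 48271 + as.double(offset)) %% 2147483647
}

irpaq_log <- function(...) {
  message("[irpaq] ", ...)
}

#' Convert genomic ranges to a BED-style data frame
#'
#' Exports 1-based closed `GRanges` coordinates to the 0-based half-open
#' convention used by BED and bedGraph files. This is the single exit point
#' for coordinate conversion; the matching entry point is the rtracklayer
#' importers used by the readers.
#'
#' @param gr A `GRanges` object.
#' @param name Optional character vector for the BED name column.
#' @param score Optional numeric vector for the BED score column.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; `start` is 0-based, `end` exclusive.
#' @export
as_bed_df <- function(gr, name = NULL, score = NULL) {
  stopifnot(is(gr, "GRanges"))
  n <- length(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(name)) rep(".", n) else as.character(name),
    score = if (is.null(score)) rep(0, n) else score,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

write_bed_df <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

write_tsv <- function(df, path, row.names = FALSE) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = row.names, col.names = TRUE
  )
  invisible(path)
}
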