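#' Read a stranded per-base coverage track from bedGraph
#'
#' Loads one bedGraph file as the coverage of one strand. bedGraph intervals
#' are 0-based half-open on disk and converted by the importer; internally
#' coverage is held as one run-length encoded vector per chromosome.
#' Positions outside any interval have depth 0. Overlapping intervals on one
#' strand are rejected.
#'
#' @param path Path to a bedGraph file.
#' @param strand `"+"` or `"-"`: the strand the file describes.
#' @return A `CoverageTrack`: list with element `strands`, a list mapping
#'   strand to a named list of per-chromosome `Rle` depth vectors.
#' @export
read_coverage_track <- function(path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1L)) == 0L) {
    return(new_coverage_track(stats::setNames(list(list()), strand)))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(is.na(gr$score)) || any(gr$score < 0)) {
    stop("bedGraph values must be numeric and >= 0: ", path, call. = FALSE)
  }
  gr <- sort(gr)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0L) {
    stop("overlapping intervals in bedGraph ", path, call. = FALSE)
  }
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  new_coverage_track(stats::setNames(list(as.list(cov)), strand))
}

new_coverage_track <- function(strands) {
  structure(list(strands = strands), class = "CoverageTrack")
}

#' Combine per-strand coverage tracks into one stranded track
#'
#' @param plus,minus `CoverageTrack` objects holding the `+` and `-` strand
#'   coverage (either may be `NULL`).
#' @return A `CoverageTrack` with both strands.
#' @export
combine_coverage_tracks <- function(plus = NULL, minus = NULL) {
  strands <- list()
  if (!is.null(plus)) strands[["+"]] <- plus$strands[["+"]]
  if (!is.null(minus)) strands[["-"]] <- minus$strands[["-"]]
  new_coverage_track(strands)
}

track_rle <- function(track, chrom, strand) {
  stopifnot(inherits(track, "CoverageTrack"))
  s <- track$strands[[strand]]
  if (is.null(s) || is.null(s[[chrom]])) {
    return(NULL)
  }
  s[[chrom]]
}

#' Per-position read depth over an interval
#'
#' @param track A `CoverageTrack`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based closed interval bounds.
#' @return Numeric vector of depths, length `end - start + 1`; positions not
#'   covered by any interval (including whole chromosomes or strands absent
#'   from the track) return 0.
#' @export
coverage_depth <- function(track, chrom, strand, start, end) {
  stopifnot(start >= 1, end >= start)
  n <- end - start + 1L
  r <- track_rle(track, chrom, strand)
  if (is.null(r)) {
    return(numeric(n))
  }
  len <- length(r)
  out <- numeric(n)
  upto <- min(end, len)
  if (upto >= start) {
    out[seq_len(upto - start + 1L)] <-
      as.numeric(S4Vectors::window(r, start, upto))
  }
  out
}

#' @export
print.CoverageTrack <- function(x, ...) {
  for (s in names(x$strands)) {
    chroms <- names(x$strands[[s]])
    cat(
      "CoverageTrack strand", s, ":", length(chroms), "chromosome(s)",
      if (length(chroms)) paste0("(", paste(chroms, collapse = ", "), ")"), "\n"
    )
  }
  invisible(x)
}

#' Write one strand of a coverage track as bedGraph
#'
#' Runs of equal non-zero depth become one bedGraph line each, with 0-based
#' half-open coordinates.
#'
#' @param track A `CoverageTrack`.
#' @param strand Strand to export.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, strand, path) {
  s <- track$strands[[strand]]
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(s)) {
    r <- s[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf(
        "%s\t%d\t%d\t%g",
        chrom, starts[keep] - 1L, ends[keep], vals[keep]
      ), con)
    }
  }
  invisible(path)
}
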