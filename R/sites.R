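#' Read BED interval or site collections
#'
#' One reader for the three BED-borne inputs: a poly(A)-site atlas, read
#' alignments reduced to intervals, and single-nucleotide eCLIP crosslink
#' events. BED's 0-based half-open coordinates are converted at import; all
#' downstream code sees 1-based closed `GRanges`.
#'
#' @param path Path to a BED file (BED6 for `polyA` and `crosslinks`).
#' @param kind `"polyA"`, `"reads"` or `"crosslinks"`.
#' @return A `GRanges`. For `crosslinks` the records are validated to be
#'   width 1 and carry metadata columns `rbp` (from the BED name field) and
#'   `multiplicity` (from the score field; a score of 0 is read as
#'   multiplicity 1, the common convention for unweighted event files).
#' @export
read_interval_sites <- function(path, kind = c("polyA", "reads", "crosslinks")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  if (file.info(path)$size == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- rtracklayer::import(path, format = "bed")
  }
  if (kind %in% c("polyA", "crosslinks")) {
    if (length(gr) > 0L && any(as.character(GenomicRanges::strand(gr)) == "*")) {
      stop(kind, " records must be stranded (BED6): ", path, call. = FALSE)
    }
  }
  if (kind == "crosslinks") {
    if (length(gr) > 0L && any(GenomicRanges::width(gr) != 1L)) {
      stop("crosslink records must be width 1: ", path, call. = FALSE)
    }
    mult <- if ("score" %in% names(S4Vectors::mcols(gr))) {
      m <- as.numeric(gr$score)
      m[is.na(m) | m == 0] <- 1
      m
    } else {
      rep(1, length(gr))
    }
    if (any(mult < 1)) stop("crosslink multiplicities must be >= 1: ", path, call. = FALSE)
    gr$rbp <- if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name) else NA_character_
    gr$multiplicity <- mult
  }
  gr
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `genotype`, `timepoint`,
#'   `replicate`.
#' @return A validated `data.frame`; `condition` (genotype x timepoint) is
#'   added as a convenience column.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample", "genotype", "timepoint", "replicate")
  if (!all(need %in% names(df))) {
    stop(
      "sample sheet must have columns ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in sheet", call. = FALSE)
  key <- paste(df$genotype, df$timepoint, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, timepoint, replicate) triple in sheet", call. = FALSE)
  }
  df$condition <- paste(df$genotype, df$timepoint, sep = "_d")
  df
}

#' Read a gene-by-sample count table
#'
#' @param path TSV whose header names samples and whose first column names
#'   genes.
#' @param sheet Sample sheet (`data.frame` from [read_sample_sheet()]); the
#'   returned columns follow the sheet's sample order. Columns not in the
#'   sheet are dropped with a logged warning; sheet samples missing from the
#'   table are an error.
#' @return Integer matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_counts <- function(path, sheet) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE
  )
  genes <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- genes
  missing <- setdiff(sheet$sample, colnames(mat))
  if (length(missing) > 0L) {
    stop(
      "samples in sheet missing from count table: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(colnames(mat), sheet$sample)
  if (length(extra) > 0L) {
    irpaq_log(
      "dropping ", length(extra), " count-table column(s) not in sheet: ",
      paste(extra, collapse = ", ")
    )
  }
  mat <- mat[, sheet$sample, drop = FALSE]
  if (anyNA(mat)) stop("count table has missing cells", call. = FALSE)
  if (any(mat < 0)) stop("count table has negative values", call. = FALSE)
  if (any(mat != round(mat))) stop("count table has non-integer values", call. = FALSE)
  storage.mode(mat) <- "integer"
  mat
}

#' Write a count table as TSV
#'
#' @param mat Integer matrix (genes x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}
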