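#' Read a genome annotation and derive introns and 3'UTRs
#'
#' Parses a GTF or GFF3 file with rtracklayer, keeps gene/transcript/exon
#' structure, and derives per-transcript introns (the gaps between
#' consecutive exons) and a single 3'UTR span per transcript. 3'UTRs are
#' taken from annotated `three_prime_utr`/`three_prime_UTR` features when
#' present; otherwise they are derived as the part of the terminal exon
#' downstream of the annotated stop codon. Transcripts with neither are
#' excluded from APA analysis with a logged warning.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param dialect `"auto"` (by file extension), `"gtf"` or `"gff3"`.
#' @return A `GenomeAnnotation` object: a list with elements
#'   \describe{
#'     \item{genes}{`GRanges` of gene spans, names are gene ids.}
#'     \item{transcripts}{`data.frame` mapping `transcript_id` to `gene_id`.}
#'     \item{exons}{`GRangesList`, one element per transcript, exons sorted
#'       in genomic order.}
#'     \item{introns}{`GRanges` with metadata `transcript_id` and `ordinal`
#'       (numbered 5' to 3' in transcript orientation).}
#'     \item{utr3}{`GRanges` with metadata `transcript_id`, one span per
#'       transcript that has a 3'UTR.}
#'   }
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  format <- switch(dialect,
    auto = if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "gtf",
    gtf = "gtf",
    gff3 = "gff3"
  )
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  build_annotation(gr, source = path)
}

# Assemble a GenomeAnnotation from a flat feature GRanges (as returned by
# rtracklayer::import on GTF/GFF3). Unknown feature types are ignored.
build_annotation <- function(gr, source = "<in-memory>") {
  type <- as.character(gr$type)
  tx_id <- annotation_tx_ids(gr)
  gene_id <- annotation_gene_ids(gr, tx_id)

  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon records in ", source, call. = FALSE)
  if (anyNA(tx_id[is_exon])) {
    stop("exon record without a transcript attribute in ", source, call. = FALSE)
  }
  exons <- gr[is_exon]
  exon_tx <- tx_id[is_exon]
  exon_gene <- gene_id[is_exon]

  if (any(as.character(GenomicRanges::strand(exons)) == "*")) {
    stop("unstranded exon record; stranded annotation required", call. = FALSE)
  }

  exons_by_tx <- S4Vectors::split(granges_bare(exons), exon_tx)
  exons_by_tx <- endoapply_sort(exons_by_tx)
  validate_exon_chains(exons_by_tx)

  tx_tab <- unique(data.frame(
    transcript_id = exon_tx,
    gene_id = exon_gene,
    stringsAsFactors = FALSE
  ))
  tx_tab <- tx_tab[order(tx_tab$transcript_id), , drop = FALSE]
  rownames(tx_tab) <- NULL

  gene_ranges <- unlist(range(S4Vectors::split(granges_bare(exons), exon_gene)))
  gene_ranges <- gene_ranges[order(names(gene_ranges))]

  introns <- derive_introns(exons_by_tx)
  utr3 <- derive_utr3(gr, type, tx_id, exons_by_tx)

  ann <- structure(
    list(
      genes = gene_ranges,
      transcripts = tx_tab,
      exons = exons_by_tx,
      introns = introns,
      utr3 = utr3
    ),
    class = "GenomeAnnotation"
  )
  ann
}

annotation_tx_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if ("transcript_id" %in% names(mc)) {
    return(as.character(mc$transcript_id))
  }
  if ("Parent" %in% names(mc)) {
    parent <- vapply(mc$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    return(sub("^transcript:", "", parent))
  }
  rep(NA_character_, length(gr))
}

annotation_gene_ids <- function(gr, tx_id) {
  mc <- S4Vectors::mcols(gr)
  if ("gene_id" %in% names(mc) && !all(is.na(mc$gene_id))) {
    return(as.character(mc$gene_id))
  }
  # GFF3: exon Parent is the transcript; find each transcript's Parent gene
  type <- as.character(gr$type)
  is_tx <- type %in% c("transcript", "mRNA")
  if (any(is_tx) && all(c("ID", "Parent") %in% names(mc))) {
    ids <- sub("^transcript:", "", as.character(mc$ID[is_tx]))
    parents <- vapply(mc$Parent[is_tx], function(p) {
      if (length(p) == 0) NA_character_ else sub("^gene:", "", as.character(p[[1]]))
    }, character(1))
    map <- stats::setNames(parents, ids)
    return(unname(map[tx_id]))
  }
  rep(NA_character_, length(gr))
}

granges_bare <- function(gr) {
  S4Vectors::mcols(gr) <- NULL
  gr
}

endoapply_sort <- function(grl) {
  S4Vectors::endoapply(grl, function(g) g[order(GenomicRanges::start(g))])
}

validate_exon_chains <- function(exons_by_tx) {
  for (tx in names(exons_by_tx)) {
    g <- exons_by_tx[[tx]]
    if (length(unique(as.character(GenomicRanges::seqnames(g)))) > 1L ||
      length(unique(as.character(GenomicRanges::strand(g)))) > 1L) {
      stop("transcript ", tx, " has exons on multiple chromosomes or strands",
        call. = FALSE
      )
    }
    if (length(g) > 1L) {
      s <- GenomicRanges::start(g)
      e <- GenomicRanges::end(g)
      if (any(s[-1L] <= e[-length(e)])) {
        stop("transcript ", tx, " has overlapping exons", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

derive_introns <- function(exons_by_tx) {
  pieces <- lapply(names(exons_by_tx), function(tx) {
    g <- exons_by_tx[[tx]]
    if (length(g) < 2L) {
      return(NULL)
    }
    s <- GenomicRanges::end(g)[-length(g)] + 1L
    e <- GenomicRanges::start(g)[-1L] - 1L
    minus <- as.character(GenomicRanges::strand(g)[1L]) == "-"
    n <- length(s)
    ord <- if (minus) rev(seq_len(n)) else seq_len(n)
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(g)[1L],
      ranges = IRanges::IRanges(start = s, end = e),
      strand = GenomicRanges::strand(g)[1L],
      transcript_id = tx,
      ordinal = ord
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    return(GenomicRanges::GRanges(transcript_id = character(0), ordinal = integer(0)))
  }
  out <- do.call(c, pieces)
  out[order(out$transcript_id, out$ordinal)]
}

derive_utr3 <- function(gr, type, tx_id, exons_by_tx) {
  is_utr <- type %in% c("three_prime_utr", "three_prime_UTR")
  utr_list <- list()
  if (any(is_utr)) {
    utr_tx <- tx_id[is_utr]
    spans <- unlist(range(S4Vectors::split(granges_bare(gr[is_utr]), utr_tx)))
    utr_list <- stats::setNames(
      lapply(seq_along(spans), function(i) spans[i]),
      names(spans)
    )
  }
  # fall back to stop_codon derivation for transcripts without UTR records
  is_stop <- type == "stop_codon"
  missing_tx <- setdiff(names(exons_by_tx), names(utr_list))
  if (any(is_stop) && length(missing_tx) > 0L) {
    stop_tx <- tx_id[is_stop]
    for (tx in intersect(missing_tx, stop_tx)) {
      g <- exons_by_tx[[tx]]
      sc <- gr[is_stop][stop_tx == tx]
      minus <- as.character(GenomicRanges::strand(g)[1L]) == "-"
      term <- if (minus) g[1L] else g[length(g)]
      span <- if (minus) {
        IRanges::IRanges(
          start = GenomicRanges::start(term),
          end = min(GenomicRanges::start(sc)) - 1L
        )
      } else {
        IRanges::IRanges(
          start = max(GenomicRanges::end(sc)) + 1L,
          end = GenomicRanges::end(term)
        )
      }
      if (IRanges::width(span) > 0L) {
        utr_list[[tx]] <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(term), span, GenomicRanges::strand(term)
        )
      }
    }
  }
  n_missing <- length(setdiff(names(exons_by_tx), names(utr_list)))
  if (n_missing > 0L) {
    irpaq_log(
      n_missing, " transcript(s) without an annotated 3'UTR or stop codon; ",
      "excluded from APA analysis"
    )
  }
  if (length(utr_list) == 0L) {
    return(GenomicRanges::GRanges(transcript_id = character(0)))
  }
  out <- do.call(c, unname(utr_list))
  out$transcript_id <- names(utr_list)
  out[order(out$transcript_id)]
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(
    "GenomeAnnotation:", length(x$genes), "genes,",
    nrow(x$transcripts), "transcripts,",
    sum(lengths(x$exons)), "exons,",
    length(x$introns), "introns,",
    length(x$utr3), "3'UTRs\n"
  )
  invisible(x)
}

#' Write a GenomeAnnotation back to GTF
#'
#' Emits exon and `three_prime_utr` records with `gene_id` and
#' `transcript_id` attributes, in 1-based inclusive GTF coordinates.
#' A read/write/read round trip preserves all coordinate sets.
#'
#' @param ann A `GenomeAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  gene_of <- stats::setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
  lines <- character(0)
  fmt <- function(g, type, tx) {
    sprintf(
      "%s\tirpaq\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      as.character(GenomicRanges::seqnames(g)), type,
      GenomicRanges::start(g), GenomicRanges::end(g),
      as.character(GenomicRanges::strand(g)),
      gene_of[[tx]], tx
    )
  }
  for (tx in names(ann$exons)) {
    g <- ann$exons[[tx]]
    for (i in seq_along(g)) lines <- c(lines, fmt(g[i], "exon", tx))
  }
  if (length(ann$utr3) > 0L) {
    for (i in seq_along(ann$utr3)) {
      lines <- c(lines, fmt(ann$utr3[i], "three_prime_utr", ann$utr3$transcript_id[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
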