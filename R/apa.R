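#' Detect continuously transcribed fragments from stranded coverage
#'
#' The genome is tiled in non-overlapping windows of `window` nt; a window
#' passes when more than `min_positions` of its positions have read depth of
#' at least `min_cov`. Consecutive passing windows are merged into
#' fragments. When a set of low-mappability intervals is supplied, passing
#' runs separated only by such intervals are also merged.
#'
#' @param track A `CoverageTrack`.
#' @param min_cov Minimum per-position depth (default 7 reads).
#' @param min_positions A window passes when strictly more than this many
#'   positions qualify (default 80).
#' @param window Window width in nt (default 100).
#' @param mappability_gaps Optional `GRanges` of low-mappability intervals.
#' @return `GRanges` of fragments (strand set, metadata `mean_cov`), sorted;
#'   fragments on one strand never overlap.
#' @export
detect_transcribed_fragments <- function(track, min_cov = 7, min_positions = 80,
                                         window = 100L, mappability_gaps = NULL) {
  stopifnot(inherits(track, "CoverageTrack"), window > min_positions)
  out <- list()
  for (s in sort(names(track$strands))) {
    for (chrom in sort(names(track$strands[[s]]))) {
      r <- track$strands[[s]][[chrom]]
      len <- length(r)
      if (len == 0L) next
      n_win <- ceiling(len / window)
      qual <- S4Vectors::Rle(as.integer(r >= min_cov))
      pad <- n_win * window - len
      if (pad > 0L) qual <- c(qual, S4Vectors::Rle(0L, pad))
      counts <- IRanges::viewSums(
        IRanges::Views(qual, start = seq(1L, n_win * window, by = window), width = window)
      )
      pass <- which(counts > min_positions)
      if (length(pass) == 0L) next
      win_ranges <- IRanges::IRanges(
        start = (pass - 1L) * window + 1L,
        width = window
      )
      frags <- IRanges::reduce(win_ranges)
      if (!is.null(mappability_gaps)) {
        frags <- merge_over_gaps(frags, mappability_gaps, chrom, s)
      }
      gr <- GenomicRanges::GRanges(chrom, frags, strand = s)
      gr$mean_cov <- vapply(seq_along(gr), function(i) {
        mean(coverage_depth(
          track, chrom, s,
          GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]
        ))
      }, numeric(1))
      out[[length(out) + 1L]] <- gr
    }
  }
  if (length(out) == 0L) {
    return(GenomicRanges::GRanges(mean_cov = numeric(0)))
  }
  # per-chromosome pieces carry disjoint seqlevels; merging them is the point
  sort(suppressWarnings(do.call(c, out)))
}

merge_over_gaps <- function(frags, mappability_gaps, chrom, strand) {
  if (length(frags) < 2L) {
    return(frags)
  }
  gaps_gr <- mappability_gaps[
    as.character(GenomicRanges::seqnames(mappability_gaps)) == chrom &
      as.character(GenomicRanges::strand(mappability_gaps)) %in% c(strand, "*")
  ]
  if (length(gaps_gr) == 0L) {
    return(frags)
  }
  gap_ir <- IRanges::reduce(IRanges::ranges(gaps_gr))
  repeat {
    between <- IRanges::gaps(
      frags,
      start = min(IRanges::start(frags)), end = max(IRanges::end(frags))
    )
    if (length(between) == 0L) {
      return(frags)
    }
    fully_low_map <- vapply(seq_along(between), function(i) {
      ov <- IRanges::intersect(between[i], gap_ir)
      sum(IRanges::width(ov)) == IRanges::width(between[i])
    }, logical(1))
    if (!any(fully_low_map)) {
      return(frags)
    }
    frags <- IRanges::reduce(c(frags, between[fully_low_map]))
  }
}

#' Extend annotated 3'UTRs using transcribed fragments
#'
#' Fragments overlapping an annotated 3'UTR on the same strand extend its 3'
#' end to the fragment end when that lies downstream. Orphan fragments (no
#' overlap with any annotated exon or 3'UTR) are associated with the closest
#' 3'UTR when (1) that UTR is the nearest annotated feature, (2) strands
#' match and (3) the distance is at most `max_distance`. A proposed
#' extension that would overlap an exon of a same-strand transcript of a
#' different gene is rejected (guard against reading into neighbouring
#' transcription units).
#'
#' @param fragments `GRanges` from [detect_transcribed_fragments()].
#' @param ann A `GenomeAnnotation`.
#' @param max_distance Maximum orphan-association distance in nt
#'   (default 10000).
#' @return `GRanges` of 3'UTRs (metadata `transcript_id`, `extended`), one
#'   per transcript with an annotated 3'UTR.
#' @export
extend_utrs <- function(fragments, ann, max_distance = 10000L) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  utrs <- ann$utr3
  if (length(utrs) == 0L) {
    return(utrs)
  }
  exons_flat <- unlist(ann$exons)
  exons_flat$transcript_id <- rep(names(ann$exons), lengths(ann$exons))
  gene_of <- stats::setNames(ann$transcripts$gene_id, ann$transcripts$transcript_id)
  exons_flat$gene_id <- unname(gene_of[exons_flat$transcript_id])

  # candidate fragment ends per UTR: overlap + qualifying orphans
  cand_end <- rep(NA_integer_, length(utrs))
  cand_start <- rep(NA_integer_, length(utrs))
  ov <- GenomicRanges::findOverlaps(utrs, fragments,
    ignore.strand = FALSE
  )
  for (i in seq_along(ov)) {
    u <- S4Vectors::queryHits(ov)[i]
    f <- fragments[S4Vectors::subjectHits(ov)[i]]
    cand_end[u] <- max(cand_end[u], GenomicRanges::end(f), na.rm = TRUE)
    cand_start[u] <- min(cand_start[u], GenomicRanges::start(f), na.rm = TRUE)
  }
  # for the nearest-feature rule, exons are trimmed of the 3'UTR spans they
  # contain (a UTR is part of its terminal exon, which would otherwise tie
  # every nearest-feature lookup)
  exon_parts <- GenomicRanges::setdiff(
    granges_bare(exons_flat), granges_bare(utrs),
    ignore.strand = FALSE
  )
  features <- c(exon_parts, granges_bare(utrs))
  feature_is_utr <- c(
    rep(FALSE, length(exon_parts)),
    rep(TRUE, length(utrs))
  )
  u_index <- c(rep(NA_integer_, length(exon_parts)), seq_along(utrs))
  orphan <- which(IRanges::overlapsAny(fragments, features, ignore.strand = TRUE) == FALSE)
  for (f in orphan) {
    frag <- fragments[f]
    d <- GenomicRanges::distance(frag, features, ignore.strand = TRUE)
    d[is.na(d)] <- Inf
    nearest_d <- min(d)
    if (!is.finite(nearest_d) || nearest_d > max_distance) next
    nearest <- which(d == nearest_d)
    if (!all(feature_is_utr[nearest])) next # nearest feature must be nothing but a 3'UTR
    hits <- nearest[as.character(GenomicRanges::strand(features[nearest])) ==
      as.character(GenomicRanges::strand(frag))]
    if (length(hits) == 0L) next
    u <- u_index[hits[1L]]
    cand_end[u] <- max(cand_end[u], GenomicRanges::end(frag), na.rm = TRUE)
    cand_start[u] <- min(cand_start[u], GenomicRanges::start(frag), na.rm = TRUE)
  }

  extended <- rep(FALSE, length(utrs))
  for (u in seq_along(utrs)) {
    minus <- as.character(GenomicRanges::strand(utrs)[u]) == "-"
    new_end <- if (minus) NA_integer_ else cand_end[u]
    new_start <- if (minus) cand_start[u] else NA_integer_
    ext_range <- NULL
    if (!minus && !is.na(new_end) && new_end > GenomicRanges::end(utrs)[u]) {
      ext_range <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(utrs)[u],
        IRanges::IRanges(GenomicRanges::end(utrs)[u] + 1L, new_end),
        strand = GenomicRanges::strand(utrs)[u]
      )
    } else if (minus && !is.na(new_start) && new_start < GenomicRanges::start(utrs)[u]) {
      ext_range <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(utrs)[u],
        IRanges::IRanges(new_start, GenomicRanges::start(utrs)[u] - 1L),
        strand = GenomicRanges::strand(utrs)[u]
      )
    }
    if (is.null(ext_range)) next
    tx <- utrs$transcript_id[u]
    other <- exons_flat[exons_flat$gene_id != gene_of[[tx]]]
    blocked <- IRanges::overlapsAny(ext_range, other, ignore.strand = FALSE)
    if (blocked) next
    if (minus) {
      GenomicRanges::start(utrs)[u] <- GenomicRanges::start(ext_range)
    } else {
      GenomicRanges::end(utrs)[u] <- GenomicRanges::end(ext_range)
    }
    extended[u] <- TRUE
  }
  utrs$extended <- extended
  if (any(extended)) irpaq_log("extended ", sum(extended), " / ", length(utrs), " 3'UTRs")
  utrs
}

#' Quantify tandem poly(A) isoforms by terminal windows
#'
#' Intersects each (possibly extended) 3'UTR with the poly(A)-site atlas;
#' transcripts with at least two sites form a tandem pair — the 5'-most
#' (proximal) and 3'-most (distal) site in transcript orientation. Each
#' site's terminal window is the `window_len` nt immediately 5' of (and
#' including) the site, truncated at the UTR start or the upstream site so
#' windows never overlap. A read is counted for the window containing its
#' 5' end.
#'
#' @param utrs `GRanges` of 3'UTRs with `transcript_id` metadata (from
#'   [extend_utrs()] or `ann$utr3`).
#' @param atlas `GRanges` of poly(A) sites (stranded, from
#'   [read_interval_sites()]).
#' @param reads Named list (by sample) of `GRanges` read intervals.
#' @param window_len Terminal window length in nt (default 300).
#' @return An `IsoformPairTable`: list with `pairs` (per-transcript
#'   geometry), `proximal` and `distal` count matrices (transcripts x
#'   samples), and `excluded` (transcripts with < 2 atlas sites).
#' @export
quantify_isoforms <- function(utrs, atlas, reads, window_len = 300L) {
  stopifnot(length(utrs) > 0L, is.list(reads), length(reads) > 0L)
  samples <- names(reads)
  pairs <- list()
  excluded <- character(0)
  for (u in seq_along(utrs)) {
    utr <- utrs[u]
    strand_u <- as.character(GenomicRanges::strand(utr))
    sites <- atlas[IRanges::overlapsAny(atlas, utr, ignore.strand = FALSE)]
    if (length(sites) < 2L) {
      excluded <- c(excluded, utr$transcript_id)
      next
    }
    pos <- GenomicRanges::end(sites) # site coordinate (width-1 or take 3' end)
    minus <- strand_u == "-"
    if (minus) pos <- GenomicRanges::start(sites)
    prox <- if (minus) max(pos) else min(pos)
    dist <- if (minus) min(pos) else max(pos)
    us <- GenomicRanges::start(utr)
    ue <- GenomicRanges::end(utr)
    if (!minus) {
      pw <- c(max(us, prox - window_len + 1L), prox)
      dw <- c(max(prox + 1L, dist - window_len + 1L), dist)
    } else {
      pw <- c(prox, min(ue, prox + window_len - 1L))
      dw <- c(dist, min(prox - 1L, dist + window_len - 1L))
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      transcript_id = utr$transcript_id,
      chrom = as.character(GenomicRanges::seqnames(utr)),
      strand = strand_u,
      utr_start = us, utr_end = ue,
      proximal_site = prox, distal_site = dist,
      prox_win_start = pw[1], prox_win_end = pw[2],
      distal_win_start = dw[1], distal_win_end = dw[2],
      stringsAsFactors = FALSE
    )
  }
  if (length(excluded) > 0L) {
    irpaq_log(length(excluded), " transcript(s) with < 2 tandem poly(A) sites excluded")
  }
  if (length(pairs) == 0L) stop("no transcript has >= 2 tandem poly(A) sites", call. = FALSE)
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- pairs$transcript_id

  n <- nrow(pairs)
  prox_m <- dist_m <- matrix(0L, n, length(samples),
    dimnames = list(pairs$transcript_id, samples)
  )
  # a read belongs to the window containing its 5' end (transcript
  # orientation), counted via stranded width-1 overlap
  prox_win <- GenomicRanges::GRanges(
    pairs$chrom, IRanges::IRanges(pairs$prox_win_start, pairs$prox_win_end),
    strand = pairs$strand
  )
  dist_win <- GenomicRanges::GRanges(
    pairs$chrom, IRanges::IRanges(pairs$distal_win_start, pairs$distal_win_end),
    strand = pairs$strand
  )
  for (s in samples) {
    rd <- reads[[s]]
    minus_rd <- as.character(GenomicRanges::strand(rd)) == "-"
    fp <- ifelse(minus_rd, GenomicRanges::end(rd), GenomicRanges::start(rd))
    fp_gr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(rd), IRanges::IRanges(fp, width = 1L),
      strand = GenomicRanges::strand(rd)
    )
    prox_m[, s] <- GenomicRanges::countOverlaps(prox_win, fp_gr, ignore.strand = FALSE)
    dist_m[, s] <- GenomicRanges::countOverlaps(dist_win, fp_gr, ignore.strand = FALSE)
  }
  structure(
    list(pairs = pairs, proximal = prox_m, distal = dist_m, excluded = excluded),
    class = "IsoformPairTable"
  )
}

#' Gate reliably expressed 3'UTR isoforms
#'
#' Reuses the two-component mixture machinery on the per-sample log2
#' terminal-window counts (proximal and distal windows pooled): the
#' low-mean component is background transcription. An isoform is expressed
#' in a condition when its posterior probability of background is below
#' `threshold` in every replicate of that condition.
#'
#' @param tab An `IsoformPairTable`.
#' @param sheet Sample sheet covering the count columns.
#' @param threshold Background-posterior threshold (default 0.01).
#' @return `tab` with an added `expressed` element: list of two logical
#'   matrices (`proximal`, `distal`; transcripts x conditions).
#' @export
gate_expressed_isoforms <- function(tab, sheet, threshold = 0.01) {
  stopifnot(inherits(tab, "IsoformPairTable"))
  samples <- sheet$sample
  n <- nrow(tab$pairs)
  p_bg_prox <- p_bg_dist <- matrix(NA_real_, n, length(samples),
    dimnames = list(rownames(tab$pairs), samples)
  )
  for (s in samples) {
    vals <- log2(c(tab$proximal[, s], tab$distal[, s]) + 1)
    fit <- fit_two_component_mixture(vals)
    p_bg <- fit$posterior[, "non_expressed"]
    p_bg_prox[, s] <- p_bg[seq_len(n)]
    p_bg_dist[, s] <- p_bg[n + seq_len(n)]
  }
  conditions <- unique(sheet$condition)
  expr_flag <- function(p_bg) {
    out <- matrix(NA, n, length(conditions),
      dimnames = list(rownames(tab$pairs), conditions)
    )
    for (cond in conditions) {
      cs <- sheet$sample[sheet$condition == cond]
      out[, cond] <- apply(p_bg[, cs, drop = FALSE] < threshold, 1L, all)
    }
    out
  }
  tab$expressed <- list(proximal = expr_flag(p_bg_prox), distal = expr_flag(p_bg_dist))
  tab
}

#' Score and classify proximal/distal poly(A) shifts between two conditions
#'
#' Counts are summed over the replicates of each condition. With condition 1
#' as the reference and condition 2 as the test:
#' S1 = log2(I_p/I_d) in condition 1 minus log2(I_p/I_d) in condition 2
#' (pseudocount 1 on each count, S1 only); S2 is the difference of proximal
#' usage proportions I_p/(I_p + I_d), computed on raw sums, so S2 is in
#' \[-1, 1\]. Significance comes from the two-sided Fisher exact test on
#' the raw summed 2x2 table (proximal/distal x condition), BH-adjusted
#' across all tested genes. Class is `proximal` when S1 <= -s1_min,
#' S2 <= -s2_min and q < `fdr` (increased proximal usage in the test
#' condition), `distal` for the mirrored thresholds, else `none`.
#'
#' @param tab An `IsoformPairTable`, ideally gated with
#'   [gate_expressed_isoforms()] (then only genes whose two isoforms are
#'   both expressed in at least one of the two conditions are tested).
#' @param sheet Sample sheet.
#' @param cond1,cond2 Reference and test condition labels.
#' @param s1_min,s2_min,fdr Classification thresholds (defaults 1, 0.15,
#'   0.01).
#' @return An `APAShiftRecord` `data.frame`: `transcript_id`, `s1`, `s2`,
#'   `p_value`, `q_value`, `class`.
#' @export
score_and_classify_shifts <- function(tab, sheet, cond1, cond2,
                                      s1_min = 1, s2_min = 0.15, fdr = 0.01) {
  stopifnot(inherits(tab, "IsoformPairTable"))
  s1s <- sheet$sample[sheet$condition == cond1]
  s2s <- sheet$sample[sheet$condition == cond2]
  if (length(s1s) == 0L || length(s2s) == 0L) {
    stop("both conditions need >= 1 sample", call. = FALSE)
  }
  ip1 <- rowSums(tab$proximal[, s1s, drop = FALSE])
  id1 <- rowSums(tab$distal[, s1s, drop = FALSE])
  ip2 <- rowSums(tab$proximal[, s2s, drop = FALSE])
  id2 <- rowSums(tab$distal[, s2s, drop = FALSE])
  keep <- (ip1 + id1) > 0 & (ip2 + id2) > 0
  if (!is.null(tab$expressed)) {
    both1 <- tab$expressed$proximal[, cond1] & tab$expressed$distal[, cond1]
    both2 <- tab$expressed$proximal[, cond2] & tab$expressed$distal[, cond2]
    keep <- keep & (both1 | both2)
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) irpaq_log(n_drop, " gene(s) excluded from shift testing")
  ids <- rownames(tab$pairs)[keep]
  ip1 <- ip1[keep]
  id1 <- id1[keep]
  ip2 <- ip2[keep]
  id2 <- id2[keep]
  s1 <- log2((ip1 + 1) / (id1 + 1)) - log2((ip2 + 1) / (id2 + 1))
  s2 <- ip1 / (ip1 + id1) - ip2 / (ip2 + id2)
  p <- vapply(seq_along(ids), function(i) {
    fisher_p_2x2(rbind(c(ip1[i], ip2[i]), c(id1[i], id2[i])))
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  class <- rep("none", length(ids))
  class[s1 <= -s1_min & s2 <= -s2_min & q < fdr] <- "proximal"
  class[s1 >= s1_min & s2 >= s2_min & q < fdr] <- "distal"
  structure(
    data.frame(
      transcript_id = ids, s1 = s1, s2 = s2,
      p_value = p, q_value = q, class = class,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    class = c("APAShiftRecord", "data.frame")
  )
}

#' Maximum expressed 3'UTR length per gene and condition
#'
#' Length from the UTR start to the most distal poly(A) site whose isoform
#' is gated expressed in the condition; `NA` when neither isoform is
#' expressed.
#'
#' @param tab A gated `IsoformPairTable` (see [gate_expressed_isoforms()]).
#' @return Numeric matrix (transcripts x conditions) of lengths in nt.
#' @export
max_expressed_utr_length <- function(tab) {
  stopifnot(inherits(tab, "IsoformPairTable"))
  if (is.null(tab$expressed)) stop("gate_expressed_isoforms() must run first", call. = FALSE)
  pairs <- tab$pairs
  minus <- pairs$strand == "-"
  len_to <- function(site) {
    ifelse(minus, pairs$utr_end - site + 1L, site - pairs$utr_start + 1L)
  }
  len_prox <- len_to(pairs$proximal_site)
  len_dist <- len_to(pairs$distal_site)
  conditions <- colnames(tab$expressed$proximal)
  out <- matrix(NA_real_, nrow(pairs), length(conditions),
    dimnames = list(rownames(pairs), conditions)
  )
  for (cond in conditions) {
    pe <- tab$expressed$proximal[, cond]
    de <- tab$expressed$distal[, cond]
    out[, cond] <- ifelse(de, len_dist, ifelse(pe, len_prox, NA_real_))
  }
  out
}
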