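#' Build an intron-retention event table
#'
#' @param events `data.frame` with one row per event: `event_id`, `gene_id`,
#'   `intron_length`, `exon5_length`, `exon3_length` (all lengths > 0), plus
#'   any coordinate columns.
#' @param intron_counts,exon5_counts,exon3_counts Integer matrices
#'   (events x samples) of reads on the intron and its 5'/3' flanking exons;
#'   shared dimnames, rownames = `event_id`.
#' @return An `IntronEventTable`.
#' @export
intron_event_table <- function(events, intron_counts, exon5_counts, exon3_counts) {
  stopifnot(
    all(c("event_id", "intron_length", "exon5_length", "exon3_length") %in% names(events)),
    nrow(intron_counts) == nrow(events),
    identical(dim(intron_counts), dim(exon5_counts)),
    identical(dim(intron_counts), dim(exon3_counts))
  )
  if (any(events$intron_length <= 0 | events$exon5_length <= 0 | events$exon3_length <= 0)) {
    stop("feature lengths must be > 0", call. = FALSE)
  }
  if (length(intron_counts) > 0L &&
    min(intron_counts, exon5_counts, exon3_counts) < 0) {
    stop("read counts must be >= 0", call. = FALSE)
  }
  rownames(intron_counts) <- rownames(exon5_counts) <- rownames(exon3_counts) <- events$event_id
  structure(
    list(
      events = events,
      intron = intron_counts, exon5 = exon5_counts, exon3 = exon3_counts
    ),
    class = "IntronEventTable"
  )
}

#' Read an intron event table from TSV
#'
#' Wide format: one row per event with the length columns of
#' [intron_event_table()] followed, for every sample `s` in the sheet, by
#' columns `intron.s`, `exon5.s`, `exon3.s`.
#'
#' @param path TSV path.
#' @param sheet Sample sheet.
#' @return An `IntronEventTable`.
#' @export
read_intron_events <- function(path, sheet) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  pull <- function(prefix) {
    cols <- paste0(prefix, ".", sheet$sample)
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0L) {
      stop("missing count columns: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[, cols, drop = FALSE])
    colnames(m) <- sheet$sample
    m
  }
  meta_cols <- setdiff(names(df), grep("^(intron|exon5|exon3)\\.", names(df), value = TRUE))
  intron_event_table(df[, meta_cols, drop = FALSE], pull("intron"), pull("exon5"), pull("exon3"))
}

#' Write an intron event table as TSV (inverse of [read_intron_events()])
#' @param tab An `IntronEventTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_events <- function(tab, path) {
  df <- tab$events
  for (prefix in c("intron", "exon5", "exon3")) {
    m <- tab[[prefix]]
    colnames(m) <- paste0(prefix, ".", colnames(m))
    df <- cbind(df, as.data.frame(m))
  }
  write_tsv(df, path)
}

#' Percent intron retention per event and sample
#'
#' IR% = 100 * (N_i / L_i) / ((N_5 / L_5 + N_3 / L_3) / 2): the
#' length-normalised intron read density relative to the mean flanking-exon
#' read density. The statistic is invariant under uniform scaling of all
#' counts and may exceed 100. Samples where both flanking exons have zero
#' reads are undefined and returned as `NA` (count logged).
#'
#' @param tab An `IntronEventTable`.
#' @return Numeric matrix (events x samples) of percent retention.
#' @export
percent_retention <- function(tab) {
  stopifnot(inherits(tab, "IntronEventTable"))
  ev <- tab$events
  intron_density <- tab$intron / ev$intron_length
  exon_density <- (tab$exon5 / ev$exon5_length + tab$exon3 / ev$exon3_length) / 2
  undef <- tab$exon5 == 0 & tab$exon3 == 0
  if (any(undef)) {
    irpaq_log(sum(undef), " event-sample cell(s) with zero flanking-exon reads set to NA")
  }
  ir <- 100 * intron_density / exon_density
  ir[undef] <- NA_real_
  ir
}

# Two-sided Fisher exact p for a 2x2 table of non-negative counts.
# An all-zero (or single-margin-zero) table carries no evidence: p = 1.
fisher_p_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Differential intron retention between two conditions
#'
#' Counts are pooled by summation over the replicates of each condition; the
#' 2x2 table per event has rows {intron reads, summed flanking-exon reads}
#' and columns {condition A, condition B}, tested with the two-sided Fisher
#' exact test. An event is called significant when the absolute difference
#' of mean percent retention between the conditions is at least `dpsi_min`
#' percentage points AND p < `alpha`.
#'
#' @param tab An `IntronEventTable`.
#' @param sheet Sample sheet for the columns of `tab`.
#' @param cond_a,cond_b Condition labels (values of `sheet$condition`).
#' @param dpsi_min Minimum |mean delta IR| in percentage points (default 10).
#' @param alpha Fisher p-value threshold (default 0.01).
#' @return `data.frame` per event: `event_id`, `ir_a`, `ir_b`, `delta_ir`
#'   (A - B), `p_value`, `significant`.
#' @export
differential_ir <- function(tab, sheet, cond_a, cond_b, dpsi_min = 10, alpha = 0.01) {
  stopifnot(inherits(tab, "IntronEventTable"))
  sa <- sheet$sample[sheet$condition == cond_a]
  sb <- sheet$sample[sheet$condition == cond_b]
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("both conditions need >= 1 sample", call. = FALSE)
  }
  ir <- percent_retention(tab)
  ir_a <- rowMeans(ir[, sa, drop = FALSE], na.rm = TRUE)
  ir_b <- rowMeans(ir[, sb, drop = FALSE], na.rm = TRUE)
  exon <- tab$exon5 + tab$exon3
  n_ev <- nrow(tab$events)
  p <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    p[i] <- fisher_p_2x2(rbind(
      c(sum(tab$intron[i, sa]), sum(tab$intron[i, sb])),
      c(sum(exon[i, sa]), sum(exon[i, sb]))
    ))
  }
  delta <- ir_a - ir_b
  data.frame(
    event_id = tab$events$event_id,
    ir_a = ir_a, ir_b = ir_b, delta_ir = delta,
    p_value = p,
    significant = !is.na(delta) & abs(delta) >= dpsi_min & p < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Coverage filter standing in for manual curation of IR events
#'
#' Keeps events whose mean flanking-exon read density — (N5/L5 + N3/L3) / 2,
#' in reads per nucleotide — reaches `min_exon_density` in at least
#' `min_samples_fraction` of the samples. Kept/dropped counts are logged.
#'
#' @param tab An `IntronEventTable`.
#' @param min_exon_density Minimum mean flanking-exon density (default 0.05
#'   reads/nt).
#' @param min_samples_fraction Fraction of samples that must pass
#'   (default 1.0 = all samples).
#' @return The filtered `IntronEventTable`.
#' @export
curate_events <- function(tab, min_exon_density = 0.05, min_samples_fraction = 1.0) {
  stopifnot(inherits(tab, "IntronEventTable"))
  if (nrow(tab$events) == 0L) {
    return(tab)
  }
  ev <- tab$events
  density <- (tab$exon5 / ev$exon5_length + tab$exon3 / ev$exon3_length) / 2
  frac_pass <- rowMeans(density >= min_exon_density)
  keep <- frac_pass >= min_samples_fraction
  irpaq_log("curate_events: kept ", sum(keep), " / ", length(keep), " events")
  intron_event_table(
    ev[keep, , drop = FALSE],
    tab$intron[keep, , drop = FALSE],
    tab$exon5[keep, , drop = FALSE],
    tab$exon3[keep, , drop = FALSE]
  )
}

#' Standardise an IR matrix row-wise
#'
#' Each event row is centred and scaled to unit *population* standard
#' deviation (divisor n, not n - 1), the convention used for relative IR
#' heatmaps. Constant rows map to all zeros (count logged).
#'
#' @param ir Numeric matrix (events x samples), >= 2 samples.
#' @return Matrix of the same shape, rows standardised.
#' @export
standardize_ir_matrix <- function(ir) {
  if (ncol(ir) < 2L) stop("need >= 2 samples per row", call. = FALSE)
  mu <- rowMeans(ir)
  centred <- ir - mu
  pop_sd <- sqrt(rowMeans(centred^2))
  const <- pop_sd == 0 | is.na(pop_sd)
  if (any(const)) irpaq_log(sum(const), " constant row(s) set to zero")
  pop_sd[const] <- 1
  out <- centred / pop_sd
  out[const, ] <- 0
  out
}
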