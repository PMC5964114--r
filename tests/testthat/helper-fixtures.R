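# Fixtures are built in code at test time; nothing binary ships with the
# package.

gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
  sprintf(
    "%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    chrom, type, start, end, strand, gene, tx
  )
}

# 3 genes / 5 transcripts / 14 exons; every transcript is a single chain, so
# the derived intron count is 14 - 5 = 9. gene2 sits on the minus strand.
write_three_gene_gtf <- function(path) {
  lines <- c(
    gtf_line("chr1", "exon", 100, 200, "+", "gene1", "tx1"),
    gtf_line("chr1", "exon", 300, 400, "+", "gene1", "tx1"),
    gtf_line("chr1", "exon", 500, 600, "+", "gene1", "tx1"),
    gtf_line("chr1", "exon", 100, 200, "+", "gene1", "tx2"),
    gtf_line("chr1", "exon", 500, 650, "+", "gene1", "tx2"),
    gtf_line("chr2", "exon", 1000, 1100, "-", "gene2", "tx3"),
    gtf_line("chr2", "exon", 1300, 1400, "-", "gene2", "tx3"),
    gtf_line("chr2", "exon", 1600, 1700, "-", "gene2", "tx3"),
    gtf_line("chr2", "exon", 1900, 2000, "-", "gene2", "tx3"),
    gtf_line("chr2", "exon", 1000, 2000, "-", "gene2", "tx4"),
    gtf_line("chr3", "exon", 10, 50, "+", "gene3", "tx5"),
    gtf_line("chr3", "exon", 80, 120, "+", "gene3", "tx5"),
    gtf_line("chr3", "exon", 200, 260, "+", "gene3", "tx5"),
    gtf_line("chr3", "exon", 300, 340, "+", "gene3", "tx5")
  )
  writeLines(lines, path)
  path
}

# independent oracle: count introns straight off the GTF text, one pass,
# without the package parser
count_introns_by_line <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t")
  tx <- vapply(fields, function(f) {
    if (f[3] != "exon") {
      return(NA_character_)
    }
    sub('.*transcript_id "([^"]+)".*', "\\1", f[9])
  }, character(1))
  tab <- table(tx[!is.na(tx)])
  sum(pmax(tab - 1L, 0L))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

make_sheet <- function(genotypes = "control", timepoints = 0, replicates = 1) {
  irpaq:::sim_sheet(genotypes, timepoints, replicates)
}

# one-event IntronEventTable with explicit counts per sample
one_event_table <- function(n_i, n_5, n_3, l_i = 1000, l_5 = 200, l_3 = 200,
                            samples = paste0("s", seq_along(n_i))) {
  m <- function(x) matrix(x, 1L, length(x), dimnames = list(NULL, samples))
  intron_event_table(
    data.frame(
      event_id = "e1", gene_id = "g1",
      intron_length = l_i, exon5_length = l_5, exon3_length = l_3
    ),
    m(n_i), m(n_5), m(n_3)
  )
}

# brute-force two-sided Fisher p by hypergeometric enumeration (the
# standard "probabilities not exceeding the observed one" definition, with
# the usual 1 + 1e-7 relative tolerance for float ties)
fisher_oracle <- function(a, b, c, d) {
  m <- a + c
  n2 <- b + d
  k <- a + b
  if (m + n2 == 0 || k == 0 || (c + d) == 0 || m == 0 || n2 == 0) {
    return(1)
  }
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
}

# run the APA pipeline end to end on a simulation and score against truth
run_apa_pipeline <- function(sim) {
  frags <- detect_transcribed_fragments(sim$track)
  utrs <- extend_utrs(frags, sim$annotation)
  tab <- quantify_isoforms(utrs, sim$atlas, sim$reads)
  tab <- gate_expressed_isoforms(tab, sim$sheet)
  res <- score_and_classify_shifts(tab, sim$sheet, sim$conditions[1], sim$conditions[2])
  list(frags = frags, utrs = utrs, tab = tab, res = res)
}

plus_track <- function(lines) {
  read_coverage_track(write_lines_tmp(lines, ".bedgraph"), "+")
}

dir_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) unname(tools::md5sum(f)), character(1))
}
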