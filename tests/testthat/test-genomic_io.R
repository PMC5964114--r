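test_that("introns are derived in 0-based half-open BED coordinates", {
  path <- write_lines_tmp(c(
    gtf_line("chr1", "exon", 100, 200, "+", "g", "t"),
    gtf_line("chr1", "exon", 300, 400, "+", "g", "t")
  ), ".gtf")
  ann <- read_annotation(path)
  expect_equal(length(ann$introns), 1L)
  bed <- as_bed_df(ann$introns)
  expect_equal(bed$start, 200)
  expect_equal(bed$end, 299)
  expect_equal(bed$end - bed$start, 99)
})

test_that("single-exon transcripts yield zero introns", {
  path <- write_lines_tmp(gtf_line("chr1", "exon", 100, 200, "+", "g", "t"), ".gtf")
  ann <- read_annotation(path)
  expect_equal(length(ann$introns), 0L)
})

test_that("derived intron count matches an independent line-by-line parse", {
  path <- tempfile(fileext = ".gtf")
  write_three_gene_gtf(path)
  ann <- read_annotation(path)
  expect_equal(length(ann$genes), 3L)
  expect_equal(nrow(ann$transcripts), 5L)
  expect_equal(sum(lengths(ann$exons)), 14L)
  expect_equal(length(ann$introns), count_introns_by_line(path))
  expect_equal(length(ann$introns), 9L)
})

test_that("minus-strand intron ordinals run 5' to 3' in transcript orientation", {
  path <- tempfile(fileext = ".gtf")
  write_three_gene_gtf(path)
  ann <- read_annotation(path)
  i3 <- ann$introns[ann$introns$transcript_id == "tx3"]
  # on the minus strand the rightmost intron is the first
  expect_equal(
    GenomicRanges::start(i3)[order(i3$ordinal)],
    sort(GenomicRanges::start(i3), decreasing = TRUE)
  )
})

test_that("overlapping exons are a validation error naming the transcript", {
  path <- write_lines_tmp(c(
    gtf_line("chr1", "exon", 100, 300, "+", "g", "bad_tx"),
    gtf_line("chr1", "exon", 250, 400, "+", "g", "bad_tx")
  ), ".gtf")
  expect_error(read_annotation(path), "bad_tx")
})

test_that("annotation round-trips through write_annotation", {
  path <- tempfile(fileext = ".gtf")
  write_three_gene_gtf(path)
  ann <- read_annotation(path)
  out <- tempfile(fileext = ".gtf")
  write_annotation(ann, out)
  ann2 <- read_annotation(out)
  expect_equal(as_bed_df(unlist(ann$exons)), as_bed_df(unlist(ann2$exons)))
  expect_equal(as_bed_df(ann$introns), as_bed_df(ann2$introns))
  expect_equal(as_bed_df(ann$utr3), as_bed_df(ann2$utr3))
})

test_that("GFF3 dialect produces the same structure as GTF", {
  gtf <- tempfile(fileext = ".gtf")
  write_three_gene_gtf(gtf)
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t600\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t100\t600\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttest\texon\t100\t200\t.\t+\t.\tParent=tx1",
    "chr1\ttest\texon\t300\t400\t.\t+\t.\tParent=tx1",
    "chr1\ttest\texon\t500\t600\t.\t+\t.\tParent=tx1"
  ), ".gff3")
  ann <- read_annotation(gff, dialect = "gff3")
  expect_equal(length(ann$introns), 2L)
  expect_equal(ann$transcripts$gene_id, "gene1")
  bed <- as_bed_df(ann$introns)
  expect_equal(bed$start, c(200, 400))
  expect_equal(bed$end, c(299, 499))
})

test_that("3'UTRs fall back to stop-codon derivation", {
  path <- write_lines_tmp(c(
    gtf_line("chr1", "exon", 100, 200, "+", "g", "t"),
    gtf_line("chr1", "exon", 300, 500, "+", "g", "t"),
    gtf_line("chr1", "stop_codon", 330, 332, "+", "g", "t")
  ), ".gtf")
  ann <- read_annotation(path)
  expect_equal(length(ann$utr3), 1L)
  expect_equal(GenomicRanges::start(ann$utr3), 333L)
  expect_equal(GenomicRanges::end(ann$utr3), 500L)
})

test_that("bedGraph semantics: interval value inside, zero outside, errors on overlap", {
  path <- write_lines_tmp("chr1\t0\t10\t5", ".bedgraph")
  track <- read_coverage_track(path, "+")
  expect_equal(coverage_depth(track, "chr1", "+", 1, 10), rep(5, 10))
  expect_equal(coverage_depth(track, "chr1", "+", 11, 11), 0)
  expect_equal(coverage_depth(track, "chr1", "-", 1, 5), rep(0, 5))
  expect_equal(coverage_depth(track, "chrX", "+", 1, 5), rep(0, 5))

  empty <- write_lines_tmp(character(0), ".bedgraph")
  t2 <- read_coverage_track(empty, "+")
  expect_equal(coverage_depth(t2, "chr1", "+", 1, 100), rep(0, 100))

  overlap <- write_lines_tmp(c("chr1\t0\t10\t5", "chr1\t5\t15\t3"), ".bedgraph")
  expect_error(read_coverage_track(overlap, "+"), "overlap")
})

test_that("bedGraph round-trips through write_bedgraph", {
  path <- write_lines_tmp(c("chr1\t0\t10\t5", "chr1\t20\t30\t2"), ".bedgraph")
  track <- read_coverage_track(path, "+")
  out <- tempfile(fileext = ".bedgraph")
  write_bedgraph(track, "+", out)
  t2 <- read_coverage_track(out, "+")
  expect_equal(
    coverage_depth(t2, "chr1", "+", 1, 40),
    coverage_depth(track, "chr1", "+", 1, 40)
  )
})

test_that("BED site readers validate strand and width", {
  atlas <- write_lines_tmp("chr1\t499\t500\tsite1\t0\t+", ".bed")
  gr <- read_interval_sites(atlas, "polyA")
  expect_equal(GenomicRanges::start(gr), 500L) # 1-based internal
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")

  unstranded <- write_lines_tmp("chr1\t499\t500\tsite1\t0", ".bed")
  expect_error(read_interval_sites(unstranded, "polyA"), "strand")

  wide <- write_lines_tmp("chr1\t100\t102\tRBP1\t3\t+", ".bed")
  expect_error(read_interval_sites(wide, "crosslinks"), "width 1")

  xl <- write_lines_tmp("chr1\t100\t101\tRBP1\t3\t+", ".bed")
  gx <- read_interval_sites(xl, "crosslinks")
  expect_equal(gx$multiplicity, 3)
  expect_equal(gx$rbp, "RBP1")
})

test_that("poly(A) atlas sites intersect UTRs as expected", {
  utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1999), strand = "+")
  atlas <- write_lines_tmp(c(
    "chr1\t1199\t1200\tin1\t0\t+",
    "chr1\t1899\t1900\tin2\t0\t+",
    "chr1\t2499\t2500\tout\t0\t+"
  ), ".bed")
  sites <- read_interval_sites(atlas, "polyA")
  inside <- sites[IRanges::overlapsAny(sites, utr)]
  expect_equal(sort(inside$name), c("in1", "in2"))
})

test_that("count tables validate against the sample sheet", {
  sheet <- make_sheet("control", 0, 2)
  good <- write_lines_tmp(c(
    paste(c("gene", sheet$sample), collapse = "\t"),
    "g1\t5\t7", "g2\t0\t3"
  ), ".tsv")
  mat <- read_counts(good, sheet)
  expect_identical(dim(mat), c(2L, 2L))
  expect_identical(mat["g1", sheet$sample[2]], 7L)

  extra <- write_lines_tmp(c(
    paste(c("gene", sheet$sample, "stray"), collapse = "\t"),
    "g1\t5\t7\t1"
  ), ".tsv")
  expect_message(read_counts(extra, sheet), "dropping")

  short <- write_lines_tmp(c(
    paste(c("gene", sheet$sample[1]), collapse = "\t"), "g1\t5"
  ), ".tsv")
  expect_error(read_counts(short, sheet), sheet$sample[2])

  neg <- write_lines_tmp(c(
    paste(c("gene", sheet$sample), collapse = "\t"), "g1\t-1\t2"
  ), ".tsv")
  expect_error(read_counts(neg, sheet), "negative")

  frac <- write_lines_tmp(c(
    paste(c("gene", sheet$sample), collapse = "\t"), "g1\t1.5\t2"
  ), ".tsv")
  expect_error(read_counts(frac, sheet), "non-integer")
})

test_that("sample sheets reject duplicate condition triples", {
  df <- data.frame(
    sample = c("a", "b"), genotype = "control", timepoint = 0, replicate = 1
  )
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(path), "duplicate")
})
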