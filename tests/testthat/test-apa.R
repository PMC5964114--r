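test_that("window rule: [0,250) coverage yields exactly fragment [0,200)", {
  track <- plus_track("chr1\t0\t250\t10")
  frags <- detect_transcribed_fragments(track)
  expect_equal(length(frags), 1L)
  bed <- as_bed_df(frags)
  expect_equal(bed$start, 0)
  expect_equal(bed$end, 200)
  # stated defaults: 7 reads / 80 positions / 100-bp windows
  f <- formals(detect_transcribed_fragments)
  expect_equal(f$min_cov, 7)
  expect_equal(f$min_positions, 80)
  expect_equal(f$window, 100L)
})

test_that("fragment detection edge cases", {
  expect_equal(length(detect_transcribed_fragments(plus_track("chr1\t0\t300\t3"))), 0L)
  # exactly 80 qualifying positions is not enough (rule is strictly more)
  t80 <- plus_track("chr1\t0\t80\t10")
  expect_equal(length(detect_transcribed_fragments(t80)), 0L)
  t81 <- plus_track("chr1\t0\t81\t10")
  expect_equal(length(detect_transcribed_fragments(t81)), 1L)
})

test_that("fragment detection is idempotent and order-invariant over chromosomes", {
  a <- plus_track(c("chr1\t0\t250\t10", "chr2\t100\t400\t9"))
  b <- plus_track(c("chr2\t100\t400\t9", "chr1\t0\t250\t10"))
  fa <- detect_transcribed_fragments(a)
  fb <- detect_transcribed_fragments(b)
  expect_equal(as_bed_df(fa), as_bed_df(fb))
  expect_equal(as_bed_df(detect_transcribed_fragments(a)), as_bed_df(fa))
})

test_that("passing runs separated only by low-mappability intervals merge", {
  track <- plus_track(c("chr1\t0\t200\t10", "chr1\t300\t500\t10"))
  plain <- detect_transcribed_fragments(track)
  expect_equal(length(plain), 2L)
  gaps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300), strand = "+")
  merged <- detect_transcribed_fragments(track, mappability_gaps = gaps)
  expect_equal(length(merged), 1L)
  expect_equal(as_bed_df(merged)$end, 500)
})

extension_fixture <- function() {
  lines <- c(
    gtf_line("chr1", "exon", 1000, 2000, "+", "geneA", "txA"),
    gtf_line("chr1", "three_prime_utr", 1500, 2000, "+", "geneA", "txA")
  )
  read_annotation(write_lines_tmp(lines, ".gtf"))
}

test_that("fragments overlapping a UTR extend its 3' end", {
  ann <- extension_fixture()
  frag <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1600, 3000), strand = "+")
  utrs <- suppressMessages(extend_utrs(frag, ann))
  expect_true(utrs$extended)
  expect_equal(GenomicRanges::end(utrs), 3000L)
  expect_equal(GenomicRanges::start(utrs), 1500L)
})

test_that("orphan fragments associate only under the three-part rule", {
  ann <- extension_fixture()
  # 5 kb downstream, same strand, nearest feature is the UTR: associated
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7000, 7400), strand = "+")
  u1 <- suppressMessages(extend_utrs(near, ann))
  expect_true(u1$extended)
  expect_equal(GenomicRanges::end(u1), 7400L)
  # beyond the 10 kb cap: not associated
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(17000, 17400), strand = "+")
  expect_false(extend_utrs(far, ann)$extended)
  # opposite strand: never associated
  anti <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7000, 7400), strand = "-")
  expect_false(extend_utrs(anti, ann)$extended)
})

test_that("extensions crossing another gene's exon are rejected", {
  lines <- c(
    gtf_line("chr1", "exon", 1000, 2000, "+", "geneA", "txA"),
    gtf_line("chr1", "three_prime_utr", 1500, 2000, "+", "geneA", "txA"),
    gtf_line("chr1", "exon", 2500, 2900, "+", "geneB", "txB"),
    gtf_line("chr1", "three_prime_utr", 2800, 2900, "+", "geneB", "txB")
  )
  ann <- read_annotation(write_lines_tmp(lines, ".gtf"))
  frag <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1600, 3000), strand = "+")
  utrs <- extend_utrs(frag, ann)
  utrA <- utrs[utrs$transcript_id == "txA"]
  expect_false(utrA$extended)
  expect_equal(GenomicRanges::end(utrA), 2000L)
})

quantify_fixture <- function() {
  utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
    strand = "+", transcript_id = "tx1"
  )
  atlas <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1400, 2000), width = 1),
    strand = "+"
  )
  list(utr = utr, atlas = atlas)
}

test_that("terminal windows count reads by 5'-end containment", {
  fx <- quantify_fixture()
  starts <- c(
    sample(1101:1351, 120, replace = TRUE), # 5' ends inside proximal window
    sample(1701:1951, 60, replace = TRUE) # inside distal window
  )
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 50), strand = "+")
  tab <- quantify_isoforms(fx$utr, fx$atlas, list(s1 = reads))
  expect_equal(unname(tab$proximal[, "s1"]), 120L)
  expect_equal(unname(tab$distal[, "s1"]), 60L)
  # no reads at all
  none <- GenomicRanges::GRanges()
  tab0 <- quantify_isoforms(fx$utr, fx$atlas, list(s1 = none))
  expect_equal(sum(tab0$proximal) + sum(tab0$distal), 0L)
})

test_that("windows truncate at the UTR start and the upstream site", {
  utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400),
    strand = "+", transcript_id = "tx1"
  )
  atlas <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1100, 1400), width = 1),
    strand = "+"
  )
  tab <- quantify_isoforms(utr, atlas, list(s1 = GenomicRanges::GRanges()))
  p <- tab$pairs
  expect_equal(p$prox_win_start, 1001) # truncated at UTR start
  expect_equal(p$prox_win_end, 1100)
  expect_equal(p$distal_win_start, 1101) # truncated at the upstream site
  expect_equal(p$distal_win_end, 1400)
  expect_lt(p$prox_win_end, p$distal_win_start)
})

test_that("transcripts with fewer than two atlas sites are excluded", {
  fx <- quantify_fixture()
  one_site <- fx$atlas[1]
  expect_error(
    suppressMessages(quantify_isoforms(fx$utr, one_site, list(s1 = GenomicRanges::GRanges()))),
    "tandem"
  )
})

shift_table <- function(prox, distal, samples) {
  pairs <- data.frame(
    transcript_id = rownames(prox), chrom = "chr1", strand = "+",
    utr_start = 1, utr_end = 1000, proximal_site = 300, distal_site = 1000,
    prox_win_start = 1, prox_win_end = 300,
    distal_win_start = 701, distal_win_end = 1000,
    stringsAsFactors = FALSE, row.names = rownames(prox)
  )
  structure(
    list(pairs = pairs, proximal = prox, distal = distal, excluded = character(0)),
    class = "IsoformPairTable"
  )
}

test_that("S1 and S2 reproduce the worked shift example", {
  sheet <- make_sheet(c("control", "mutant"), 0, 1)
  prox <- matrix(c(80L, 20L), 1, 2, dimnames = list("tx1", sheet$sample))
  dist <- matrix(c(20L, 80L), 1, 2, dimnames = list("tx1", sheet$sample))
  tab <- shift_table(prox, dist, sheet$sample)
  res <- score_and_classify_shifts(tab, sheet, "control_d0", "mutant_d0")
  expect_equal(res$s1, 2 * log2(81 / 21), tolerance = 1e-12)
  expect_equal(res$s1, 3.8949, tolerance = 1e-4)
  expect_equal(res$s2, 0.6, tolerance = 1e-12)
  expect_lt(abs(res$p_value - fisher_oracle(80, 20, 20, 80)), 1e-10)
  expect_identical(res$class, "distal")

  # identical usage: both scores zero, class none
  same <- shift_table(
    matrix(c(50L, 50L), 1, 2, dimnames = list("tx1", sheet$sample)),
    matrix(c(70L, 70L), 1, 2, dimnames = list("tx1", sheet$sample)),
    sheet$sample
  )
  r0 <- score_and_classify_shifts(same, sheet, "control_d0", "mutant_d0")
  expect_equal(r0$s1, 0)
  expect_equal(r0$s2, 0)
  expect_identical(r0$class, "none")
})

test_that("shift scores are antisymmetric and S2 is bounded on random tables", {
  set.seed(44)
  sheet <- make_sheet(c("control", "mutant"), 0, 1)
  n <- 1000
  ids <- sprintf("t%04d", 1:n)
  prox <- matrix(as.integer(stats::rpois(2 * n, 60)), n, 2, dimnames = list(ids, sheet$sample))
  dist <- matrix(as.integer(stats::rpois(2 * n, 60)), n, 2, dimnames = list(ids, sheet$sample))
  tab <- shift_table(prox, dist, sheet$sample)
  ab <- suppressMessages(score_and_classify_shifts(tab, sheet, "control_d0", "mutant_d0"))
  ba <- suppressMessages(score_and_classify_shifts(tab, sheet, "mutant_d0", "control_d0"))
  expect_identical(ab$transcript_id, ba$transcript_id)
  expect_equal(ab$s1, -ba$s1, tolerance = 1e-12)
  expect_equal(ab$s2, -ba$s2, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_true(all(ab$s2 >= -1 & ab$s2 <= 1))
  expect_true(all(is.finite(ab$s1)))
})

test_that("genes with zero counts in a condition are excluded with a log", {
  sheet <- make_sheet(c("control", "mutant"), 0, 1)
  prox <- matrix(c(0L, 30L, 10L, 40L), 2, 2, dimnames = list(c("t1", "t2"), sheet$sample))
  dist <- matrix(c(0L, 30L, 10L, 40L), 2, 2, dimnames = list(c("t1", "t2"), sheet$sample))
  tab <- shift_table(prox, dist, sheet$sample)
  expect_message(
    res <- score_and_classify_shifts(tab, sheet, "control_d0", "mutant_d0"),
    "excluded"
  )
  expect_identical(res$transcript_id, "t2")
})

test_that("isoform gating recovers planted background isoforms", {
  sim <- simulate_apa_coverage(simulation_config(seed = 1))
  tab <- suppressMessages(quantify_isoforms(sim$annotation$utr3, sim$atlas, sim$reads))
  tab <- gate_expressed_isoforms(tab, sim$sheet)
  tr <- sim$truth[match(rownames(tab$pairs), sim$truth$transcript_id), ]
  conds <- colnames(tab$expressed$distal)
  distal_expressed <- tab$expressed$distal[, conds[1]] | tab$expressed$distal[, conds[2]]
  expect_gte(f1_score(distal_expressed, !tr$distal_background), 0.95)
  # proximal isoforms are always expressed in this design
  expect_gte(mean(tab$expressed$proximal), 0.95)
  # a zero-count isoform is always background
  zero_tx <- rownames(tab$pairs)[1]
  tab$distal[zero_tx, ] <- 0L
  tab2 <- gate_expressed_isoforms(tab, sim$sheet)
  expect_false(any(tab2$expressed$distal[zero_tx, ]))
})

test_that("maximum expressed UTR length follows the gated sites", {
  sheet <- make_sheet(c("control", "mutant"), 0, 1)
  prox <- matrix(c(50L, 50L), 1, 2, dimnames = list("tx1", sheet$sample))
  dist <- matrix(c(40L, 40L), 1, 2, dimnames = list("tx1", sheet$sample))
  tab <- shift_table(prox, dist, sheet$sample)
  expect_error(max_expressed_utr_length(tab), "gate")
  tab$expressed <- list(
    proximal = matrix(c(TRUE, TRUE), 1, 2, dimnames = list("tx1", c("control_d0", "mutant_d0"))),
    distal = matrix(c(FALSE, TRUE), 1, 2, dimnames = list("tx1", c("control_d0", "mutant_d0")))
  )
  len <- max_expressed_utr_length(tab)
  expect_equal(unname(len["tx1", "control_d0"]), 300) # only proximal expressed
  expect_equal(unname(len["tx1", "mutant_d0"]), 1000) # distal expressed
  tab$expressed$proximal[1, 1] <- FALSE
  expect_true(is.na(max_expressed_utr_length(tab)["tx1", "control_d0"]))
})

test_that("planted UTR lengthening yields a monotone median over conditions", {
  conds <- c("control_d0", "control_d7", "control_d14")
  n <- 20
  ids <- sprintf("t%02d", 1:n)
  pairs <- data.frame(
    transcript_id = ids, chrom = "chr1", strand = "+",
    utr_start = 1, utr_end = 1000, proximal_site = 300, distal_site = 1000,
    prox_win_start = 1, prox_win_end = 300,
    distal_win_start = 701, distal_win_end = 1000,
    row.names = ids, stringsAsFactors = FALSE
  )
  # progressively more genes express the distal isoform at later timepoints
  distal_expr <- cbind(
    rep(c(TRUE, FALSE), c(4, 16)),
    rep(c(TRUE, FALSE), c(10, 10)),
    rep(c(TRUE, FALSE), c(18, 2))
  )
  dimnames(distal_expr) <- list(ids, conds)
  tab <- structure(
    list(
      pairs = pairs,
      proximal = matrix(50L, n, 3, dimnames = list(ids, paste0(conds, "_r1"))),
      distal = matrix(10L, n, 3, dimnames = list(ids, paste0(conds, "_r1"))),
      expressed = list(
        proximal = matrix(TRUE, n, 3, dimnames = list(ids, conds)),
        distal = distal_expr
      )
    ),
    class = "IsoformPairTable"
  )
  med <- apply(max_expressed_utr_length(tab), 2L, stats::median, na.rm = TRUE)
  expect_true(all(diff(med) >= 0))
  expect_gt(med[3], med[1])
})
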