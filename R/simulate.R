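#' Simulation configuration
#'
#' One seeded configuration object drives all four generators. Defaults
#' encode the study conditions the generators emulate: a 2-genotype
#' (control / mutant) x 5-timepoint (0, 7, 14, 21, 35 days) x 2-replicate
#' grid, bimodal log2 counts (non-expressed N(0.5, 0.7^2), expressed
#' N(6, 1.2^2), 40% non-expressed), three low-rank temporal programmes
#' (monotone ramp, early transient bump, late step), Poisson intron/exon
#' read counts with condition-specific retention, two-poly(A)-site 3'UTR
#' coverage from 50-nt reads, and per-RBP Poisson crosslink tracks with a
#' planted retained-intron enrichment.
#'
#' @param seed Mandatory integer master seed.
#' @param ... Named overrides of any default; nested lists (`grid`,
#'   `mixture`, `programmes`, `ir`, `apa`, `eclip`) are merged field-wise.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  defaults <- list(
    seed = seed,
    n_genes = 2000L,
    frac_nonexpressed = 0.4,
    grid = list(
      genotypes = c("control", "mutant"),
      timepoints = c(0, 7, 14, 21, 35),
      replicates = 2L
    ),
    mixture = list(
      nonexpr_mean = 0.5, nonexpr_sd = 0.7,
      expr_mean = 6, expr_sd = 1.2
    ),
    programmes = list(
      n_components = 3L,
      genes_per_set = 100L, # per sign, per programme
      effect_sizes = c(3, 2, 1.4), # log2 amplitude per programme
      noise_sd = 0.3,
      dispersion = 0.05
    ),
    ir = list(
      n_events = 200L,
      n_diff = 30L,
      intron_length = 1000L,
      exon_length = 200L,
      exon_density = 0.5, # reads per nt per sample
      base_retention = c(0.05, 0.35), # uniform range for the shared baseline
      delta_retention = 0.2 # added in mutant conditions for n_diff events
    ),
    apa = list(
      n_genes = 200L,
      n_shift = 30L,
      prop_shift = c(0.25, 0.75), # proximal usage: reference, test
      prop_null = c(0.35, 0.65), # uniform range for non-shifted genes
      frac_background = 0.3, # genes whose distal isoform is background-level
      prop_background = 0.98, # proximal usage for background-distal genes
      depth = 200L, # expected reads per UTR per sample
      read_len = 50L,
      utr_len = 600L, # proximal site at 300, distal at utr_len
      proximal_at = 300L,
      gene_spacing = 5000L,
      frac_truncated = 0.5, # genes whose annotation stops at the proximal site
      frac_minus = 0.5,
      replicates = 2L
    ),
    eclip = list(
      n_rbps = 20L,
      n_genes = 1L,
      n_introns = 6L,
      intron_length = 2000L,
      exon_length = 100L,
      intensity = 0.25, # events per nt
      retained_ordinal = 3L,
      enrichment = 8,
      enriched_rbp = "RBP01"
    )
  )
  overrides <- list(...)
  cfg <- defaults
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes > 0, cfg$frac_nonexpressed >= 0, cfg$frac_nonexpressed <= 1,
    length(cfg$grid$timepoints) >= 1, cfg$grid$replicates >= 1,
    all(cfg$ir$base_retention >= 0), all(cfg$ir$base_retention <= 1),
    cfg$ir$intron_length > 0, cfg$ir$exon_length > 0,
    cfg$ir$n_diff <= cfg$ir$n_events,
    cfg$apa$proximal_at < cfg$apa$utr_len,
    cfg$eclip$enrichment >= 0
  )
  invisible(cfg)
}

sim_sheet <- function(genotypes, timepoints, replicates) {
  grid <- expand.grid(
    replicate = seq_len(replicates),
    timepoint = timepoints,
    genotype = genotypes,
    stringsAsFactors = FALSE
  )[, c("genotype", "timepoint", "replicate")]
  grid$sample <- sprintf("%s_d%g_r%d", grid$genotype, grid$timepoint, grid$replicate)
  validate_sample_sheet(grid[, c("sample", "genotype", "timepoint", "replicate")])
}

# Temporal programme profiles over the sample grid: monotone ramp, early
# transient bump (precursor-stage peak), late step. Centred and
# orthonormalised (QR) so the SVD of a noiseless simulation recovers them
# exactly.
programme_profiles <- function(sheet) {
  t <- sheet$timepoint
  tmax <- max(t)
  raw <- cbind(
    ramp = t / tmax,
    bump = exp(-((t - 7)^2) / (2 * 5^2)),
    step = 1 / (1 + exp(-(t - 25) / 3))
  )
  centred <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(centred))
  # orient each profile to correlate positively with its raw shape
  for (k in seq_len(ncol(q))) {
    if (sum(q[, k] * centred[, k]) < 0) q[, k] <- -q[, k]
  }
  rownames(q) <- sheet$sample
  colnames(q) <- colnames(raw)[seq_len(ncol(q))]
  q
}

#' Simulate a differentiation timecourse count table
#'
#' Expressed genes get a log2 mean of baseline + sum_k loading_k *
#' programme_k(sample) + N(0, noise_sd); counts are negative binomial
#' around 2^mean (Poisson in the dispersion -> 0 limit). Non-expressed
#' genes draw their log2 mean from the low mixture component. Truth records
#' expression class, programme membership, sign and loading per gene.
#'
#' @param cfg A `SimulationConfig`.
#' @return List: `counts` (integer matrix), `sheet`, `truth` (`data.frame`
#'   gene / expressed / programme (0 = background) / sign / loading),
#'   `profiles` (samples x components, the planted orthonormal programme
#'   profiles), `mean_log2` (the noiseless log2 mean matrix).
#' @export
simulate_timecourse_counts <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (length(cfg$grid$timepoints) < 2L) {
    stop("timecourse simulation needs >= 2 timepoints", call. = FALSE)
  }
  with_seed(child_seed(cfg$seed, 101), {
    sheet <- sim_sheet(cfg$grid$genotypes, cfg$grid$timepoints, cfg$grid$replicates)
    n <- cfg$n_genes
    n_samp <- nrow(sheet)
    genes <- sprintf("G%05d", seq_len(n))
    n_non <- round(cfg$frac_nonexpressed * n)
    expressed <- c(rep(FALSE, n_non), rep(TRUE, n - n_non))

    pc <- cfg$programmes
    profiles <- programme_profiles(sheet)
    if (pc$genes_per_set > 0L && pc$n_components > ncol(profiles)) {
      stop("grid supports only ", ncol(profiles), " programme component(s)",
        call. = FALSE
      )
    }
    profiles <- profiles[, seq_len(min(pc$n_components, ncol(profiles))), drop = FALSE]
    programme <- integer(n)
    sign_vec <- integer(n)
    loading <- numeric(n)
    expr_idx <- which(expressed)
    need <- pc$n_components * 2L * pc$genes_per_set
    if (need > length(expr_idx)) stop("not enough expressed genes for programme sets", call. = FALSE)
    slot <- expr_idx[seq_len(need)]
    k_of <- rep(seq_len(pc$n_components), each = 2L * pc$genes_per_set)
    s_of <- rep(rep(c(1L, -1L), each = pc$genes_per_set), times = pc$n_components)
    programme[slot] <- k_of
    sign_vec[slot] <- s_of
    loading[slot] <- s_of * pc$effect_sizes[k_of] * stats::runif(need, 0.8, 1.2)

    mx <- cfg$mixture
    baseline <- ifelse(expressed,
      stats::rnorm(n, mx$expr_mean, mx$expr_sd),
      stats::rnorm(n, mx$nonexpr_mean, mx$nonexpr_sd)
    )
    mean_log2 <- matrix(baseline, n, n_samp)
    active <- programme > 0L
    if (any(active)) {
      load_mat <- matrix(0, n, pc$n_components)
      load_mat[cbind(which(active), programme[active])] <- loading[active]
      mean_log2 <- mean_log2 + sqrt(n_samp) * (load_mat %*% t(profiles))
    }
    mean_log2 <- pmax(mean_log2, 0)
    dimnames(mean_log2) <- list(genes, sheet$sample)

    noisy <- mean_log2 + matrix(stats::rnorm(n * n_samp, 0, pc$noise_sd), n, n_samp)
    mu <- pmax(2^noisy - 1, 1e-8)
    counts <- if (pc$dispersion > 0) {
      matrix(
        stats::rnbinom(n * n_samp, mu = mu, size = 1 / pc$dispersion),
        n, n_samp
      )
    } else {
      matrix(stats::rpois(n * n_samp, mu), n, n_samp)
    }
    dimnames(counts) <- list(genes, sheet$sample)
    storage.mode(counts) <- "integer"

    truth <- data.frame(
      gene = genes, expressed = expressed,
      programme = programme, sign = sign_vec, loading = loading,
      stringsAsFactors = FALSE
    )
    list(
      counts = counts, sheet = sheet, truth = truth,
      profiles = profiles, mean_log2 = mean_log2
    )
  })
}

#' Simulate intron-retention events with planted retention fractions
#'
#' Flanking-exon reads are Poisson(density x length); intron reads are
#' Poisson(retention x density x intron length). A subset of events gets
#' `delta_retention` added in all mutant conditions (the planted
#' differential events); truth stores the per-condition retention.
#'
#' @param cfg A `SimulationConfig`. `cfg$ir$retention_matrix`, if supplied,
#'   overrides the planted retention (events x conditions).
#' @return List: `table` (an `IntronEventTable`), `sheet`, `truth`
#'   (`data.frame` with one row per event x condition: planted retention and
#'   differential flag).
#' @export
simulate_intron_events <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(child_seed(cfg$seed, 202), {
    sheet <- sim_sheet(cfg$grid$genotypes, cfg$grid$timepoints, cfg$grid$replicates)
    conditions <- unique(sheet$condition)
    p <- cfg$ir
    n <- p$n_events
    ids <- sprintf("E%04d", seq_len(n))
    if (!is.null(p$retention_matrix)) {
      ret <- p$retention_matrix
      stopifnot(nrow(ret) == n, ncol(ret) == length(conditions))
      diff_flag <- apply(ret, 1L, function(r) max(r) - min(r) > 0)
    } else {
      base <- stats::runif(n, p$base_retention[1], p$base_retention[2])
      diff_flag <- c(rep(TRUE, p$n_diff), rep(FALSE, n - p$n_diff))
      ret <- matrix(base, n, length(conditions), dimnames = list(ids, conditions))
      if (any(diff_flag)) {
        if (length(cfg$grid$genotypes) < 2L) {
          stop("differential events need >= 2 genotypes in the grid", call. = FALSE)
        }
        mutant_conds <- conditions[startsWith(conditions, cfg$grid$genotypes[2])]
        ret[diff_flag, mutant_conds] <- pmin(ret[diff_flag, mutant_conds] + p$delta_retention, 1)
      }
    }
    dimnames(ret) <- list(ids, conditions)

    li <- rep(p$intron_length, length.out = n)
    le <- rep(p$exon_length, length.out = n)
    events <- data.frame(
      event_id = ids, gene_id = paste0("gene_", ids),
      intron_length = li, exon5_length = le, exon3_length = le,
      stringsAsFactors = FALSE
    )
    n_samp <- nrow(sheet)
    mk <- function() matrix(0L, n, n_samp, dimnames = list(ids, sheet$sample))
    intron <- e5 <- e3 <- mk()
    for (j in seq_len(n_samp)) {
      cond <- sheet$condition[j]
      e5[, j] <- stats::rpois(n, p$exon_density * le)
      e3[, j] <- stats::rpois(n, p$exon_density * le)
      intron[, j] <- stats::rpois(n, ret[, cond] * p$exon_density * li)
    }
    truth <- data.frame(
      event_id = rep(ids, times = length(conditions)),
      condition = rep(conditions, each = n),
      retention = as.vector(ret),
      differential = rep(diff_flag, times = length(conditions)),
      stringsAsFactors = FALSE
    )
    list(
      table = intron_event_table(events, intron, e5, e3),
      sheet = sheet, truth = truth
    )
  })
}

#' Simulate tandem-poly(A) 3'UTR coverage with planted shifts
#'
#' Each gene carries one single-exon transcript whose 3'UTR holds a
#' proximal site (at `proximal_at` nt) and a distal site (at `utr_len` nt).
#' Per sample, Poisson(`depth`) reads choose the proximal or distal isoform
#' according to the condition's planted proximal proportion and tile the
#' isoform uniformly with fixed-length reads. The reference condition keeps
#' the shared proportion for all genes; planted proximal-shift genes use
#' `prop_shift` (reference, test). For a configurable fraction of genes the
#' emitted annotation is deliberately truncated at the proximal site, so
#' the coverage-based 3'UTR extension step has work to do. The atlas always
#' contains both sites.
#'
#' @param cfg A `SimulationConfig`.
#' @return List: `track` (pooled `CoverageTrack`), `reads` (named list of
#'   per-sample read `GRanges`), `annotation` (`GenomeAnnotation`), `atlas`
#'   (`GRanges`), `sheet`, `truth` (`data.frame` per gene: planted class,
#'   proportions, truncation flag).
#' @export
simulate_apa_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(child_seed(cfg$seed, 303), {
    p <- cfg$apa
    sheet <- sim_sheet(cfg$grid$genotypes, 0, p$replicates)
    conditions <- unique(sheet$condition) # reference first, then test
    n <- p$n_genes
    ids <- sprintf("APA%04d", seq_len(n))

    shifted <- c(rep(TRUE, p$n_shift), rep(FALSE, n - p$n_shift))
    n_bg <- round(p$frac_background * n)
    background <- c(rep(FALSE, n - n_bg), rep(TRUE, n_bg)) & !shifted
    prop_ref <- prop_test <- stats::runif(n, p$prop_null[1], p$prop_null[2])
    prop_ref[shifted] <- p$prop_shift[1]
    prop_test[shifted] <- p$prop_shift[2]
    prop_ref[background] <- prop_test[background] <- p$prop_background
    truncated <- seq_len(n) %% round(1 / max(p$frac_truncated, 1e-9)) == 0
    if (p$frac_truncated >= 1) truncated <- rep(TRUE, n)
    minus <- stats::runif(n) < p$frac_minus

    chrom <- "chrS"
    utr_start <- (seq_len(n) - 1L) * p$gene_spacing + 1001L # aligned to 100-nt grid + 1
    utr_end <- utr_start + p$utr_len - 1L
    # site coordinates in transcript orientation
    prox <- ifelse(minus, utr_end - p$proximal_at + 1L, utr_start + p$proximal_at - 1L)
    dist <- ifelse(minus, utr_start, utr_end)

    reads <- list()
    for (s in sheet$sample) {
      cond_test <- sheet$condition[sheet$sample == s] == conditions[2]
      prop <- if (cond_test) prop_test else prop_ref
      starts_all <- integer(0)
      ends_all <- integer(0)
      strands_all <- character(0)
      for (g in seq_len(n)) {
        n_reads <- stats::rpois(1L, p$depth)
        if (n_reads == 0L) next
        is_prox <- stats::runif(n_reads) < prop[g]
        iso_len <- ifelse(is_prox, p$proximal_at, p$utr_len)
        offset <- floor(stats::runif(n_reads) * (iso_len - p$read_len + 1L))
        if (minus[g]) {
          ends <- utr_end[g] - offset
          starts <- ends - p$read_len + 1L
        } else {
          starts <- utr_start[g] + offset
          ends <- starts + p$read_len - 1L
        }
        starts_all <- c(starts_all, starts)
        ends_all <- c(ends_all, ends)
        strands_all <- c(strands_all, rep(if (minus[g]) "-" else "+", n_reads))
      }
      reads[[s]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts_all, ends_all),
        strand = strands_all
      )
    }
    pooled <- do.call(c, unname(reads))
    track <- new_coverage_track(list(
      "+" = as.list(GenomicRanges::coverage(pooled[GenomicRanges::strand(pooled) == "+"])),
      "-" = as.list(GenomicRanges::coverage(pooled[GenomicRanges::strand(pooled) == "-"]))
    ))

    # annotation: exon + 3'UTR per gene, truncated at the proximal site for
    # the designated subset
    ann_end <- ifelse(truncated & !minus, prox, utr_end)
    ann_start <- ifelse(truncated & minus, prox, utr_start)
    feat <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(rep(ann_start, 2L), rep(ann_end, 2L)),
      strand = rep(ifelse(minus, "-", "+"), 2L),
      type = rep(c("exon", "three_prime_utr"), each = n),
      gene_id = rep(ids, 2L),
      transcript_id = rep(paste0(ids, ".t1"), 2L)
    )
    annotation <- build_annotation(feat, source = "simulate_apa_coverage")

    atlas <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(c(prox, dist), width = 1L),
      strand = rep(ifelse(minus, "-", "+"), 2L),
      name = c(paste0(ids, "_prox"), paste0(ids, "_dist")),
      score = 0L
    )
    truth <- data.frame(
      transcript_id = paste0(ids, ".t1"), gene_id = ids,
      class = ifelse(shifted, "proximal", "none"),
      distal_background = background,
      prop_ref = prop_ref, prop_test = prop_test,
      truncated = truncated, strand = ifelse(minus, "-", "+"),
      stringsAsFactors = FALSE
    )
    list(
      track = track, reads = reads, annotation = annotation,
      atlas = sort(atlas), sheet = sheet, truth = truth,
      conditions = conditions
    )
  })
}

#' Simulate per-RBP crosslink tracks with a planted retained-intron signal
#'
#' Every gene's transcript has `n_introns` introns; per RBP and intron the
#' crosslink-event count is Poisson(intensity x length), with the intensity
#' on the designated retained intron multiplied by the planted enrichment
#' factor for the enriched RBP. Event positions are uniform within the
#' intron; repeated positions collapse into one record with multiplicity.
#'
#' @param cfg A `SimulationConfig`.
#' @return List: `sites` (named list by RBP of crosslink `GRanges`),
#'   `annotation` (`GenomeAnnotation`), `truth` (`data.frame` per RBP:
#'   planted enrichment factor), `retained_ordinal`.
#' @export
simulate_crosslink_sites <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(child_seed(cfg$seed, 404), {
    p <- cfg$eclip
    rbps <- sprintf("RBP%02d", seq_len(p$n_rbps))
    genes <- sprintf("CL%03d", seq_len(p$n_genes))

    # gene models: alternating exon/intron blocks on the plus strand
    feats <- list()
    intron_spans <- list()
    offset <- 1L
    for (g in genes) {
      tx <- paste0(g, ".t1")
      pos <- offset
      exon_starts <- integer(0)
      for (i in seq_len(p$n_introns + 1L)) {
        exon_starts <- c(exon_starts, pos)
        pos <- pos + p$exon_length
        if (i <= p$n_introns) pos <- pos + p$intron_length
      }
      feats[[g]] <- GenomicRanges::GRanges(
        "chrC", IRanges::IRanges(exon_starts, width = p$exon_length),
        strand = "+", type = "exon", gene_id = g, transcript_id = tx
      )
      intron_spans[[g]] <- data.frame(
        start = exon_starts[-length(exon_starts)] + p$exon_length,
        end = exon_starts[-1L] - 1L
      )
      offset <- pos + 10000L
    }
    # these gene models carry no 3'UTR records on purpose (introns are the
    # object of interest); silence the APA-exclusion note
    annotation <- suppressMessages(
      build_annotation(do.call(c, unname(feats)), source = "simulate_crosslink_sites")
    )

    sites <- list()
    for (rbp in rbps) {
      starts <- integer(0)
      for (g in genes) {
        spans <- intron_spans[[g]]
        for (i in seq_len(nrow(spans))) {
          lambda <- p$intensity * (spans$end[i] - spans$start[i] + 1L)
          if (i == p$retained_ordinal && rbp == p$enriched_rbp) {
            lambda <- lambda * p$enrichment
          }
          k <- stats::rpois(1L, lambda)
          if (k > 0L) {
            starts <- c(starts, spans$start[i] + floor(stats::runif(k) * (spans$end[i] - spans$start[i] + 1L)))
          }
        }
      }
      tab <- table(starts)
      pos <- as.integer(names(tab))
      sites[[rbp]] <- GenomicRanges::GRanges(
        "chrC", IRanges::IRanges(pos, width = 1L), strand = "+",
        rbp = rbp, multiplicity = as.integer(tab)
      )
    }
    truth <- data.frame(
      rbp = rbps,
      enrichment = ifelse(rbps == p$enriched_rbp, p$enrichment, 1),
      stringsAsFactors = FALSE
    )
    list(
      sites = sites, annotation = annotation, truth = truth,
      retained_ordinal = p$retained_ordinal, genes = genes
    )
  })
}

#' Write a simulation result set to a directory
#'
#' Emits the standard formats of the readers (TSV counts and sample sheet,
#' GTF annotation, bedGraph coverage, BED reads/atlas/crosslinks) plus
#' `truth.tsv`, so every downstream stage can be scored from files alone.
#' Identical configs produce byte-identical files.
#'
#' @param sim Output of one of the `simulate_*` generators.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$counts)) write_counts(sim$counts, file.path(dir, "counts.tsv"))
  if (!is.null(sim$sheet)) {
    write_tsv(
      sim$sheet[, c("sample", "genotype", "timepoint", "replicate")],
      file.path(dir, "samples.tsv")
    )
  }
  if (!is.null(sim$table)) write_intron_events(sim$table, file.path(dir, "ir_events.tsv"))
  if (!is.null(sim$annotation)) write_annotation(sim$annotation, file.path(dir, "annotation.gtf"))
  if (!is.null(sim$track)) {
    for (s in names(sim$track$strands)) {
      nm <- if (s == "+") "plus" else "minus"
      write_bedgraph(sim$track, s, file.path(dir, paste0("coverage_", nm, ".bedgraph")))
    }
  }
  if (!is.null(sim$atlas)) {
    write_bed_df(as_bed_df(sim$atlas, name = sim$atlas$name), file.path(dir, "polya_atlas.bed"))
  }
  if (!is.null(sim$reads)) {
    for (s in names(sim$reads)) {
      write_bed_df(
        as_bed_df(sim$reads[[s]]),
        file.path(dir, paste0("reads_", s, ".bed"))
      )
    }
  }
  if (!is.null(sim$sites)) {
    for (rbp in names(sim$sites)) {
      gr <- sim$sites[[rbp]]
      write_bed_df(
        as_bed_df(gr, name = gr$rbp, score = gr$multiplicity),
        file.path(dir, paste0("crosslinks_", rbp, ".bed"))
      )
    }
  }
  if (!is.null(sim$truth)) write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
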