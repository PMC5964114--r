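---
title: "Models and methods behind irpaq"
author: "irpaq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind irpaq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irpaq)
```

# Overview

`irpaq` implements the post-alignment analysis layer for a stranded bulk
RNA-seq timecourse of directed differentiation (an iPSC-to-motor-neuron
design with two genotypes, five timepoints, replicated libraries), together
with an eCLIP-derived protein-binding readout. Five analysis stages are
covered:

1. **Expression gating** — which genes are reliably expressed, per
   condition, via a two-component Gaussian mixture on log2 counts.
2. **Programme decomposition** — SVD of the gated, quantile-normalised
   expression matrix into temporal transcriptional programmes, and
   selection of programme-associated gene sets.
3. **Intron-retention (IR) quantification** — the percent-IR statistic per
   event and sample, with Fisher count tests for differential retention.
4. **Alternative polyadenylation (APA)** — coverage-based transcribed
   fragment detection, 3'UTR extension, terminal-window quantification of
   tandem poly(A) isoforms, and the S1/S2 shift scores.
5. **eCLIP enrichment** — crosslink-density enrichment of an RNA-binding
   protein on a designated retained intron relative to the other introns of
   the same gene.

Each stage is exercised end to end on seeded synthetic data with planted
truth; the generators are first-class, tested package code.

# Coordinate conventions

Genomic files use two conventions: GTF/GFF3 are 1-based inclusive, BED and
bedGraph are 0-based half-open. Internally `irpaq` standardises on the
Bioconductor convention — 1-based closed `GRanges`/`IRanges` — because all
interval arithmetic (overlaps, distances, coverage) goes through
`GenomicRanges`, and a private convention layered on top of it is where
off-by-one errors breed. Conversion happens exactly once per direction:
rtracklayer importers convert BED-family inputs at read time, and
`as_bed_df()` is the single exit point back to 0-based half-open output.
Every coverage, crosslink and atlas query is strand-specific; unstranded
records in stranded inputs are rejected, matching the heavily stranded
(>90%) libraries this pipeline expects.

When an annotation lacks explicit 3'UTR records, the UTR is derived as the
part of the terminal exon downstream of the annotated stop codon; a
transcript with neither is excluded from APA analysis with a logged note.

# The expression gate

For one sample, the histogram of `log2(count + 1)` is bimodal: a low mode
of non-expressed genes and a high mode of expressed genes. We fit

$$ x \sim w_1\,\mathcal N(\mu_1, \sigma_1^2) + w_2\,\mathcal N(\mu_2, \sigma_2^2), \qquad \mu_1 < \mu_2 $$

by EM with free variances, initialised by k-means on the sorted values and
taking the best of five seeded restarts (sorting plus fixed internal seeds
makes the fit deterministic and invariant to input order). Convergence is a
relative log-likelihood change below `1e-8` or 500 iterations.

Two numerical choices matter:

* **Variance floor (`sd_floor = 0.5` log2 units).** Counts are discrete,
  and a large atom of exact zeros lets one component collapse onto
  `log2(0 + 1) = 0` with unbounded likelihood. That "fit" turns the gate
  into a `count >= 1` rule. The floor forces the low component to describe
  a *mode* of low counts rather than the zero atom. Half a log2 unit is far
  narrower than any real expression mode, so the floor never binds on
  well-separated data; with the floor disabled, a collapsing fit is retried
  and eventually raises an error.
* **Per-sample fitting.** Library depth shifts both modes, so one mixture
  is fitted per sample rather than pooling.

A gene is *reliably expressed* in a condition (genotype × timepoint) when
the criterion holds in **every** sample of that condition. Two modes are
exposed and neither is declared canonical, mirroring the two thresholds in
use for gene-level and transcript-level work: `strict` requires the
posterior probability of the non-expressed component below 0.01 per sample;
`permissive` requires the posterior of the expressed component above 0.1.
The pseudocount of 1 before log2 is applied uniformly. The gate is monotone
in its threshold, and the gene universe for all downstream stages is the
union of per-condition calls.

Quantile normalisation of the count matrix is delegated to
`limma::normalizeQuantiles` (ties receive the mean of their target
quantiles). Sample clustering uses `1 -` Spearman correlation with complete
linkage, so it is invariant to monotone per-sample distortions; samples are
processed in lexicographic id order, which fixes leaf order.

# Programme decomposition

The gated, normalised, log2 matrix is gene-centred by default (otherwise
component 1 is just the grand mean) and decomposed exactly:
$X = U D V^\top$. The right singular vectors $\vec v_k$ are programme
profiles over samples; component $k$ explains $d_k^2 / \sum_i d_i^2$ of the
variance. Because SVD signs are arbitrary, each $\vec v_k$ is oriented so
its largest-magnitude entry is positive. Gene standardisation (z-scoring)
before decomposition is available behind the `scale` flag but off by
default, so high-amplitude genes keep their weight in the spectrum.

Genes are scored against a programme twice: Pearson correlation of the
gene's (centred) profile with $\vec v_k$, and projection $x_g \cdot \vec
v_k$. Both are z-scored across genes and clustered with seeded K-means; the
cluster with the highest mean standardised correlation-plus-projection is
the positively associated set, the lowest the negative set. The default is
**five** clusters (positive / weakly positive / neutral / weakly negative /
negative): with three, the single middle cluster must swallow everything
that is neither extreme, and its boundary cuts through the score cloud of
the weakest programme — on planted-truth simulations the recovered sets for
the third programme were unstable (Jaccard against truth ranging 0.4–0.9
across seeds), while five clusters keep the extreme sets pure (Jaccard
&ge; 0.88 across seeds). Genes with constant profiles have undefined
correlation and are excluded from selection with a logged count.

# Intron retention

For an event with intron length $L_i$ and flanking exon lengths $L_5, L_3$
and read counts $N_i, N_5, N_3$:

$$ \mathrm{IR\%} = 100 \cdot \frac{N_i / L_i}{\tfrac12\left(N_5/L_5 + N_3/L_3\right)} $$

— intron read density relative to mean flanking-exon density. It is
invariant under uniform depth scaling and may exceed 100 (nothing caps
intronic density at exonic density). When both flanking exons have zero
reads the statistic is undefined and reported `NA`. The alternative reading
of length normalisation — average the counts first, then divide by mean
length — is deliberately not the default; densities are averaged.

Differential IR between two conditions sums counts over replicates and
tests the 2×2 table {intron reads, summed flanking-exon reads} ×
{condition A, condition B} with the two-sided Fisher exact test
(`stats::fisher.test`; the test suite verifies agreement with brute-force
hypergeometric enumeration to `1e-10` for all small tables). An event is
called at the defaults |ΔIR| &ge; 10 percentage points **and** p &lt; 0.01.
Note the p-value, unlike IR% itself, is depth-dependent. Replicates are
pooled by summation, the natural reading of a counts-based test.

Manual curation of low-coverage events is replaced by an explicit,
parameterised filter: keep events whose mean flanking-exon density reaches
`min_exon_density` (default 0.05 reads/nt — an artifact default, not a
literature value) in at least `min_samples_fraction` of samples. IR
heatmap standardisation centres each event row and scales to unit
*population* standard deviation (divisor $n$); constant rows map to zero.

# Alternative polyadenylation

**Fragment detection.** The genome is tiled in non-overlapping 100-nt
windows; a window passes when more than 80 of its positions have depth
&ge; 7 reads, and consecutive passing windows merge into transcribed
fragments. The tiling-plus-merge reading keeps detection idempotent and
order-invariant; a sliding step is exposed for sensitivity analyses. If a
low-mappability interval set is supplied, passing runs separated only by
such intervals merge too.

**3'UTR extension.** Fragments overlapping an annotated 3'UTR on the same
strand extend its 3' end to the fragment end. Orphan fragments (overlapping
no annotated exon or UTR) are associated with the closest 3'UTR when the
nearest annotated feature is nothing but a 3'UTR, strands match and the
distance is at most 10,000 nt — the cap is read as 10 kb, the plausible
intragenic range. For the nearest-feature rule, exons are trimmed of the
UTR spans they contain, since a 3'UTR is part of its terminal exon and
would otherwise tie every lookup. An extension that would cross an exon of
a same-strand transcript of a *different* gene is rejected; this single
rule stands in for the fuller published filtering against intragenic
transcription, overlapping transcripts and retained introns, and is
documented as an approximation.

**Isoform quantification.** Atlas poly(A) sites are intersected with each
(possibly extended) UTR; transcripts with at least two sites form a tandem
pair, taking the 5'-most and 3'-most site when there are more. Each site's
terminal window is the 300 nt immediately 5' of it, truncated at the UTR
start or the upstream site, so windows never overlap; a read belongs to the
window containing its 5' end (one read, one window).

**Isoform gating** reuses the mixture machinery on per-sample log2 window
counts: the low-mean component is background transcription, and an isoform
is expressed in a condition when its background posterior is below 0.01 in
every replicate. A gene is tested for shifts only when both isoforms are
expressed in at least one of the two conditions compared.

**Shift scores.** With condition 1 the reference and counts summed over
replicates,

$$ S_1 = \log_2\!\frac{I_p}{I_d}\Big|_{1} - \log_2\!\frac{I_p}{I_d}\Big|_{2}, \qquad S_2 = \frac{I_p}{I_p + I_d}\Big|_{1} - \frac{I_p}{I_p + I_d}\Big|_{2} \in [-1, 1]. $$

A pseudocount of 1 enters $S_1$ only (keeping it finite); $S_2$ and the
Fisher test use raw sums. Significance is the two-sided Fisher exact test
on the summed 2×2 table, BH-adjusted across all tested genes. A gene is a
*proximal* shift when $S_1 \le -1$, $S_2 \le -0.15$ and q &lt; 0.01 —
i.e. increased proximal usage in the test condition — and a *distal* shift
for the mirrored thresholds. Swapping the conditions negates both scores
exactly and leaves p unchanged. The per-condition maximum expressed UTR
length is the distance from the UTR start to the most distal expressed
site, `NA` when neither isoform is expressed.

# eCLIP enrichment

Crosslink events are single-nucleotide records (by producer convention, the
coordinate immediately 5' of the reverse-transcription truncation), with
multiplicities. For a gene with a designated retained intron,

$$ \mathrm{enrichment} = \frac{(c_r + 1)/L_r}{(c_o + 1)/L_o}, $$

with $c_r, L_r$ the event count and length of the retained intron and
$c_o, L_o$ pooled over the gene's other introns — a length-normalised
density ratio, pseudocount-guarded so it is always finite and positive. An
unpooled variant (median of per-intron ratios) is available behind the
`pooled` flag. A single-intron gene has no comparator and is an error.
RBPs are ranked by descending enrichment with deterministic tie-breaks
(total event count, then name).

# The synthetic-data generators

The generators emulate the statistical structure each stage assumes, with
machine-readable truth tables sufficient to score every downstream caller.
All are pure functions of a `simulation_config(seed, ...)`; the same
config yields byte-identical output files.

* **Timecourse counts.** 2 genotypes × 5 timepoints (0, 7, 14, 21, 35
  days) × 2 replicates; 2,000 genes of which 40% are non-expressed. The
  log2 baseline of expressed genes is N(6, 1.2²), non-expressed N(0.5,
  0.7²). Three temporal programmes — monotone ramp, early transient bump
  (precursor-stage peak), late step — are centred, orthonormalised and
  planted into 100 positive plus 100 negative genes each with log2
  amplitudes 3, 2 and 1.4; remaining noise is N(0, 0.3²) plus
  negative-binomial counting noise (dispersion 0.05, Poisson in the limit
  0). Counts are negative binomial because that is the standard RNA-seq
  noise model; no specific noise model is claimed by the study this design
  mirrors, so all generator distributions are stand-ins.
* **IR events.** Flanking-exon reads are Poisson(density × length), intron
  reads Poisson(retention × density × intron length); 30 of 200 events add
  0.2 to their retention in the mutant conditions.
* **APA coverage.** 200 single-exon genes on one synthetic chromosome
  (both strands), 600-nt UTRs with a proximal site at 300 nt and a distal
  site at the UTR end, an expected 200 50-nt reads per UTR per sample whose
  5' ends tile the chosen isoform uniformly. Thirty genes shift proximal
  usage 0.25 → 0.75 between conditions; the rest draw usage from
  U(0.35, 0.65), except a 30% background class whose distal isoform runs at
  2% usage — the gate needs a real background mode to estimate, just as on
  real data where many annotated isoforms are unexpressed. Half the genes
  are emitted with their annotation deliberately truncated at the proximal
  site so the extension stage has work to do; the atlas always carries both
  sites.
* **Crosslinks.** Per RBP and intron, event counts are
  Poisson(intensity × length) with positions uniform in the intron;
  default 20 RBPs over six 2-kb introns at 0.25 events/nt, with one RBP's
  intensity on the retained intron multiplied by 8.

What the generators deliberately do **not** model: mappability and GC
structure, positional read bias inside transcripts, overdispersion of
crosslink counts, isoform complexity beyond one tandem pair per gene, and
alignment artefacts. Passing tests therefore demonstrate correctness of
the statistical machinery under its stated assumptions, not robustness to
every artefact of real libraries.

# Problem sizes and determinism

The shipped validation runs at desk scale by design: 2,000-gene
timecourses, 200-gene APA chromosomes, 5,000-event null calibrations and
200-replicate ranking experiments — large enough for the planted effects
to be comfortably in the asymptotic regime of every test used, small
enough to iterate on. Every internal stochastic step (k-means restarts,
simulators) draws from seeds derived deterministically from the master
seed without touching the caller's RNG state, so each CLI stage re-run
with the same seed and inputs is byte-identical.

# Known limitations

* The isoform windows count read-through: a distal-isoform read whose 5'
  end falls in the proximal window is counted there, as in any real
  terminal-window quantification; S2 is therefore attenuated relative to
  the true isoform-proportion difference. The planted-truth tests measure
  detection, not unbiased estimation of isoform proportions.
* The exon-overlap rejection rule is a coarse stand-in for published
  multi-step extension filtering.
* The Fisher count tests pool replicates; biological replicate variance is
  not modelled (no replicate-aware dispersion test is provided).
* Event discovery (which introns to quantify) is out of scope; events
  enter as an annotated table.
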