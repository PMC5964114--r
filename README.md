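# irpaq

Intron retention and alternative polyadenylation quantification for
stranded RNA-seq timecourses.

`irpaq` is the post-alignment analysis layer for replicated differentiation
timecourses (the motivating design: iPSC-derived motor neurons, two
genotypes × five timepoints), plus an eCLIP protein–RNA binding readout. It
is aimed at analysts who already have gene counts, per-base coverage, read
intervals and crosslink events, and need the bespoke statistics that sit on
top of them:

* **Expression gating** — per-sample two-component Gaussian mixtures on
  log2(count + 1); a gene is reliably expressed in a condition when its
  posterior probability of the non-expressed component is < 1% in every
  sample of that condition (a permissive >0.1 expressed-posterior mode is
  also provided).
* **Transcriptional programmes** — exact SVD of the gated,
  quantile-normalised log2 matrix, X = U D Vᵀ; right singular vectors v⃗_k
  are temporal programmes, and programme gene sets are selected by seeded
  K-means on standardised (correlation, projection) scores.
* **Percent intron retention** —
  IR% = 100 · (N_i/L_i) / ((N_5/L_5 + N_3/L_3)/2),
  with differential IR by two-sided Fisher exact test on replicate-summed
  counts, called at |ΔIR| ≥ 10 points and p < 0.01.
* **APA shift scoring** — transcribed-fragment detection from bedGraph
  coverage (>80 positions ≥7 reads per 100-bp window), coverage-based
  3'UTR extension (≤10 kb, strand-matched, exon-collision-guarded),
  terminal-300-nt tandem-isoform quantification, and the shift scores
  S1 = log2(I_p/I_d)|cond1 − log2(I_p/I_d)|cond2 and
  S2 = I_p/(I_p+I_d)|cond1 − I_p/(I_p+I_d)|cond2 ∈ [−1, 1],
  classified at |S1| ≥ 1, |S2| ≥ 0.15, BH q < 0.01.
* **eCLIP retained-intron enrichment** — pseudocounted crosslink-density
  ratio of a designated retained intron over the pooled remaining introns
  of the same gene, with deterministic RBP ranking.
* **Seeded synthetic-data generators** for every stage, with truth tables —
  the package validates itself end to end on planted signal.

Standard formats go through the standard tools: GTF/GFF3, BED and bedGraph
via `rtracklayer`, interval arithmetic via `GenomicRanges`, quantile
normalisation via `limma`, tests via `stats`.

## Worked example

Simulate an APA experiment with 30 planted proximal shifts among 200 genes
(half of them with deliberately truncated annotation), then run the whole
pipeline — fragment detection, UTR extension, isoform quantification,
expression gating and shift classification:

```r
library(irpaq)
cfg  <- simulation_config(seed = 42)
sim  <- simulate_apa_coverage(cfg)
frags <- detect_transcribed_fragments(sim$track)
utrs  <- extend_utrs(frags, sim$annotation)
#> [irpaq] extended 70 / 200 3'UTRs
tab  <- quantify_isoforms(utrs, sim$atlas, sim$reads)
tab  <- gate_expressed_isoforms(tab, sim$sheet)
res  <- score_and_classify_shifts(tab, sim$sheet,
                                  sim$conditions[1], sim$conditions[2])
table(res$class)
#>     none proximal
#>      108       30
head(res[res$class != "none", ][order(res$q_value[res$class != "none"]), ], 5)
#>    transcript_id    s1     s2  p_value  q_value    class
#> 1     APA0001.t1 -2.54 -0.283 1.78e-22 2.46e-20 proximal
#> 7     APA0007.t1 -2.35 -0.271 5.66e-20 3.90e-18 proximal
#> 27    APA0027.t1 -2.32 -0.246 1.28e-18 5.90e-17 proximal
#> 17    APA0017.t1 -2.20 -0.252 1.84e-17 6.33e-16 proximal
#> 8     APA0008.t1 -2.20 -0.244 3.06e-17 8.04e-16 proximal
```

All 30 planted shifts are recovered (negative S1 and S2: increased proximal
usage in the test condition), with no false calls among the nulls. The
expression gate looks like this on one simulated library:

```r
x <- log2(simulate_timecourse_counts(cfg)$counts[, "control_d0_r1"] + 1)
fit_two_component_mixture(x)
#> MixtureFit: non-expressed N(0.248, 0.500^2) w=0.334 |
#>             expressed N(5.533, 2.498^2) w=0.666 | logLik -4602.48 (converged, 25 iter)
```

Every stage is also callable from a shell through the thin wrapper
`inst/cli/irpaq.R`:

```sh
Rscript inst/cli/irpaq.R simulate apa --seed 42 --out simdir
Rscript inst/cli/irpaq.R apa --dir simdir --out shifts.tsv
```

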