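# embryodyn

Transcriptome dynamics of cloned and in vivo fertilized pre-implantation
embryos, from a gene-level count matrix to staged biology.

## What this package is for

In early mammalian development the embryo degrades its maternal transcript
store while embryonic genome activation (EGA) — in the pig, mainly between
the 2-cell and 8-cell stages — switches on its own genome. Embryos cloned by
somatic cell nuclear transfer (SCNT) must reprogram a somatic nucleus during
this window, and a delayed or damped activation wave is a key signature of
why most of them arrest. Profiling this process with bulk RNA-seq of pooled
embryos leaves the analyst with small, often unreplicated designs and a set
of threshold rules on FPKM that decide everything downstream.

`embryodyn` packages that analysis for anyone staging embryo (or other
short-time-series) transcriptomes from counts:

* **Quantification** — FPKM with the conservation identity
  `sum_i FPKM_ij * L_i = 1e9`, expressed-gene calling at FPKM ≥ 1,
  median-of-ratios size factors and trimmed-mean (TMM) scaling factors.
* **Differential expression** — the conditional binomial exact test for
  one-vs-one libraries (`k1 | k1+k2=n ~ Bin(n, N1/(N1+N2))`, adjusted
  p < 0.005 and |log2 FC| > 1), and a negative-binomial conditioned exact
  test on replicate condition sums with pooled method-of-moments dispersion
  (adjusted p < 0.05), both Benjamini–Hochberg corrected.
* **Staging** — successive-stage DEG profiles; stage-specific genes
  (FPKM > 5 at one stage, < 1 at all others); first-expressed genes
  (FPKM > 1 at a stage, < 1 at all earlier stages, significant against the
  immediate predecessor) — the operational definition of EGA timing.
* **Lineage** — inner-cell-mass marker calling from bisected blastocysts
  (FPKM < 1 in the trophectoderm half, > 10 in the ICM-containing half) and
  gene-panel trajectories (pluripotency factors, histone
  methyltransferases/demethylases) from an editable GMT.
* **QC** — hierarchical clustering on correlation distance, PCA of expressed
  genes, pairwise R² matrices.
* **Simulation** — a seeded synthetic embryo-transcriptome generator with
  planted maternal decay, zygotic activation waves, cloned-group delay and
  negative-binomial noise, plus ground truth for recovery scoring.

Everything is data-frame in, tibble out, and chains with the pipe; results
have `plot_*()`/`autoplot()` helpers and `tidy()`/`glance()` methods.

## Worked example

Simulate the replicated study design (two embryo groups at four critical
stages, three replicates, plus donor cells), quantify, and stage the
activation wave:

```r
library(embryodyn)

sim  <- simulate_experiment(sim_config(n_genes = 2000, seed = 1), "design27")
fpkm <- compute_fpkm(sim$counts, sim$annotation)

de <- run_successive_de(sim$counts, sim$sample_sheet, "IV-D")
successive_stage_degs(de)
#> # A tibble: 3 × 6
#>   group stage_from stage_to    n_up n_down n_total
#> 1 IV-D  oocyte     4-cell       771    403    1174
#> 2 IV-D  4-cell     8-cell       239    478     717
#> 3 IV-D  8-cell     blastocyst   171     32     203
```

The oocyte → 4-cell transition dominates: zygotic genes switch on (up) while
maternal transcripts decay (down), and degradation completes by the 8-cell
stage — the maternal–zygotic transition the simulator plants and the DEG
profile recovers. First-expressed calls date each gene's activation:

```r
fe <- detect_first_expressed(fpkm, de, sim$sample_sheet, "IV-D")
table(fe$stage)
#>     4-cell     8-cell blastocyst
#>        372        213        144

head(fe, 3)
#>   gene_id group  stage  fpkm_stage fpkm_prev_max padj_vs_prev
#> 1 G00002  IV-D   8-cell       73.0             0     2.06e-30
#> 2 G00004  IV-D   4-cell      770.              0     4.44e-54
#> 3 G00009  IV-D   4-cell       73.6             0     6.02e-96
```

Each called gene exceeds 1 FPKM at the reported stage, never before
(`fpkm_prev_max`), with the predecessor contrast significant. Running the
same detector on the cloned group shows the reprogramming defect: the wave
shifts from the 4-cell mode (372/213/144 across 4-cell/8-cell/blastocyst in
IV-D) toward later stages in NT-D (239/267/218) — the activation delay the
simulator plants with per-gene probability 0.4.

The whole pipeline, with every table and a reproducibility manifest:

```r
cfg <- pipeline_config(simulate = list(n_genes = 2000, design = "design27",
                                       bisect = TRUE), seed = 1)
run_pipeline(cfg, "results/run1")
```

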