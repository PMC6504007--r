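---
title: "Staging the pre-implantation embryo transcriptome: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging the pre-implantation embryo transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryodyn)
```

## The scientific problem

During the first week of mammalian development the embryo hands control from
maternally deposited transcripts to its own genome: maternal mRNAs are
degraded while embryonic genome activation (EGA) switches on transcription,
in the pig mainly between the 2-cell and 8-cell stages. Embryos produced by
somatic cell nuclear transfer (SCNT) must reprogram a differentiated nucleus
on the fly, and most arrest before implantation; a delayed or damped EGA
wave is a leading molecular signature of that failure.

`embryodyn` implements the bulk RNA-seq analysis used to characterise this
process when embryos are pooled into one library per group × stage (with at
most a handful of biological replicates): FPKM quantification, exact-test
differential expression with and without replicates, successive-stage DEG
profiling, threshold-based stage-specific and first-expressed gene
classification, inner-cell-mass (ICM) marker identification from bisected
blastocysts, gene-panel trajectories, and sample-level QC. A synthetic
embryo-transcriptome simulator with planted ground truth makes every rule
testable at desk scale.

## Quantification

Counts are converted to FPKM as

$$\mathrm{FPKM}_{ij} = \frac{k_{ij}\,10^9}{N_j\,L_i},$$

with $N_j$ the total counted fragments of sample $j$ *within the matrix*
(the pipeline never sees the aligner's mapped-read total, so reproduced
FPKMs can differ from published ones by a per-sample constant) and $L_i$ the
transcript-union exon length. The identity
$\sum_i \mathrm{FPKM}_{ij} L_i = 10^9$ holds exactly and is asserted in the
tests. A gene is called *expressed* at FPKM ≥ 1 — inclusive, whereas the
classification rules below are strict; the two conventions follow the
field's customary phrasing of each rule and are deliberately not unified.

Two normalizations are provided behind one surface:

* **median-of-ratios** size factors (the companion of the replicated
  negative-binomial test): $s_j = \mathrm{median}_i\, k_{ij} / (\prod_j
  k_{ij})^{1/m}$ over genes positive in every sample;
* **trimmed-mean (TMM) scaling factors** for unreplicated libraries: the
  inverse-variance-weighted mean of per-gene log2 ratios after trimming the
  most extreme 30% of M-values and 5% of A-values, giving an effective
  library size $\tilde N_j = N_j f_j$. When fewer than 10 genes survive
  trimming the untrimmed weighted mean is used with a warning.

## Differential expression

**Without replicates** (the 25-sample staging design) each contrast is one
library against one library. Under the null of equal relative expression,
conditioning on the total gives

$$k_1 \mid k_1 + k_2 = n \;\sim\; \mathrm{Binomial}\!\left(n,
\tilde N_1 / (\tilde N_1 + \tilde N_2)\right),$$

and the two-sided p-value doubles the smaller tail (a minimum-likelihood
rule is available by flag). This conditional exact test was chosen over a
normal MA-plot approximation because it is exact, has an enumeration oracle,
and converges to the same answer at moderate counts. Its null model is
*Poisson* sampling noise: with a single library per condition, biological
overdispersion is indistinguishable from signal, so calls from this mode
carry the usual caveat of unreplicated RNA-seq. DEGs require adjusted
p < 0.005 **and** |log2 fold change| > 1, both strict; fold changes use a
pseudocount of 1 on the counts-per-million scale, which bounds the fold
change of genes absent in one condition — the dominant case for
first-expressed genes.

**With replicates** (the 27-sample design) the two condition sums
$K_A, K_B$ are modelled as negative binomial around a pooled mean
($\mu_A = S_A q_0$, $q_0 = (K_A+K_B)/(S_A+S_B)$, $S$ the summed size
factors) with replicate-sum variance $\mu + \alpha q_0^2 \sum_j s_j^2$; the
p-value sums, over all splits $(a, b)$ of the grand total, the
probabilities of outcomes no more likely than the observed split. At
$\alpha = 0$ this reduces exactly to the conditional binomial test (asserted
to $10^{-6}$ in the acceptance suite). DEGs require adjusted p < 0.05.

Dispersion is estimated per gene by pooled method of moments,
$\hat\alpha = \max\{0, (v - m)/m^2\}$ with $m$ the grand normalized mean and
$v$ the within-condition variance pooled over replicated conditions. Three
replicates cannot support fitting a mean–dispersion trend, so no curve is
fitted; the estimator is noisy per gene (its median over genes recovers a
planted $\alpha = 0.2$ within ±50% at 3+3 replicates, the tolerance the
tests document) and slightly biased downward because the $1/s_j$ correction
term is omitted. Supplying known or externally estimated dispersions is
supported and used for the calibration checks.

Multiple testing uses Benjamini–Hochberg step-up within each contrast, with
no independent filtering by default (available by flag, with the number of
tests logged) since the original workflow does not mention it.

## Staging rules

All staging rules operate on mean FPKM per group × stage (replicates
collapsed by arithmetic mean — the natural choice when the published rule is
silent on replicate handling; the collapse is stated in every output), and
always within one group's own stage series, never across groups.

* **Stage-specific**: FPKM > 5 at exactly one stage and < 1 at every other
  stage of the series (both strict), restricted by default to genes carrying
  a name in the annotation.
* **First-expressed**: FPKM > 1 at a stage, < 1 at *all* earlier stages —
  including the oocyte when present, since maternal carryover is precisely
  what the rule must exclude — and adjusted p < 0.05 with the gene higher in
  the contrast against the immediate predecessor stage only. The earliest
  qualifying stage is reported; the first stage of a series can never be
  called. A complete series of predecessor contrasts is required; a missing
  transition is an error rather than a silently skipped comparison.
* Genes with a missing FPKM at any stage are excluded from both classifiers
  and counted in a log attribute.

Successive-stage DEG tables are oriented later-over-earlier, so "up" genes
rise at the later stage. Venn-region counts are provided for 2–3 gene sets,
and a generic one-sided Fisher (hypergeometric) over-representation test
stands in for pathway tooling; length-bias-corrected GO testing and
commercial pathway databases are out of scope.

## Lineage markers and panels

Separating ICM from TE is technically infeasible in pig blastocysts, so
blastocysts are bisected into a TE-only half and an "IT" half containing
both lineages. A gene is an ICM marker when mean FPKM < 1 in TE and > 10 in
IT (strict). Modelling IT as the mixture $\rho \cdot \mathrm{ICM} +
(1-\rho)\cdot \mathrm{TE}$, an optional model-based column back-estimates
the pure ICM level as $(\mathrm{IT} - (1-\rho)\mathrm{TE})/\rho$; the marker
rule itself uses only the raw IT/TE values. Gene panels (pluripotency
factors, H3K4/H3K9/H3K27 methyltransferases and demethylases) ship as an
editable GMT file, and trajectory extraction reports unmatched panel names
instead of dropping them.

## Sample QC

Hierarchical clustering uses average linkage on $1 - r$ (Pearson) distance
over $\log_{10}(\mathrm{FPKM} + 1)$, by default restricted to the union of
DEGs from all computed contrasts; complete and Ward linkage are available by
flag. PCA keeps genes with mean FPKM ≥ 1, log-transforms and gene-centres.
Pairwise sample similarity is the squared Pearson correlation on the same
transform over all genes. The +1 offset keeps zeros finite where the
published transform names none, and is recorded in output metadata.
Zero-variance samples are an error for clustering and reported as missing
entries (never 0) for correlations.

## The simulator

The generator plants a ground truth that the analysis is scored against.
Gene classes and their default fractions: maternal 25%, zygotic 30%,
housekeeping 20%, stage-specific 5%, ICM and TE lineage markers 2% each,
remainder silent. Its dynamics mirror the biology the staging rules target:

* maternal transcripts start at a log-normal baseline (median 20 FPKM,
  log-sd 1) and decay by a factor 0.4 per stage, reaching exactly zero at
  the 8-cell stage (the major maternal–zygotic transition);
* zygotic genes switch from exactly 0 to their baseline at an activation
  stage drawn with probabilities 0.02 / 0.55 / 0.35 / 0.06 / 0.02 over the
  2-cell … blastocyst stages, concentrating the wave on the 4-cell and
  8-cell stages in proportions resembling observed first-expression counts;
* cloned groups delay a zygotic gene's activation by one stage with
  probability δ (defaults: 0.4 for NT-D, 0.2 for NT-LW, 0 for IV-D, encoding
  the stronger reprogramming failure of the Duroc donor line) and damp
  zygotic/stage-specific expression by γ (0.6 / 0.8 / 1). A delay that would
  push activation past the blastocyst silences the gene in that group;
* lineage markers appear only at the blastocyst; an IT half carries exactly
  ρ = 0.5 of the ICM signal, a TE half none.

Counts are negative binomial, $k_{ij} \sim \mathrm{NB}(\mu_{ij} L_i D_j /
10^9, \alpha)$ with default dispersion α = 0.05 (pooled ~10-embryo libraries
average out much biological noise; embryo-to-embryo variance folds into α
rather than receiving its own term). $D_j$ is a log-normal depth *scale*
(log-sd 0.3) whose default median, $3 \times 10^6$, yields roughly
$5 \times 10^5$ counted fragments per library under the default
transcriptome — three orders of magnitude below real libraries, but
sufficient to exercise every rule at desk scale, which is what the tests
claim and no more. Gene lengths are log-uniform on [500, 10000] bp and 15%
of genes lack a name, emulating draft-annotation gaps. Every stochastic step
draws from its own RNG stream derived from the master seed by a stable
label, so adding samples never reshuffles earlier draws and runs are
bit-reproducible.

Two built-in designs reproduce the study layouts: `design27` (NT-D and IV-D
at oocyte/4-cell/8-cell/blastocyst × 3 replicates, plus 3 donor-cell
samples) and `design25` (three groups × 7 consecutive stages without
replicates, plus two donor-cell samples and two additional MII oocyte
samples — the composition that reaches the published sample total, since
enumerating groups × stages plus donors alone gives 23). Donor fibroblast
samples express the housekeeping class only; they exist to exercise sample
handling, not to model somatic transcriptomes.

### What the simulator does not emulate

True FPKM in the generator is an absolute concentration, so quantified FPKM
differs from it by a per-sample compositional factor (as real FPKM does);
recovery tests therefore compare profiles and thresholds, not absolute
levels. There is no read-level error, no isoform structure, no GC or length
bias beyond the explicit length term, no batch structure, and maternal decay
is deterministic. Passing recovery tests demonstrates that the *rules* are
implemented correctly and are recoverable under the planted dynamics — not
that real embryo libraries would yield the published gene lists.

## Numerical choices

* Exact-test p-values are computed in log space with a `logsumexp`
  normalization; outcome ties use a relative tolerance of $10^{-8}$.
* The unreplicated two-sided rule doubles the smaller tail and caps at 1;
  `k1 = k2 = 0` returns p = 1.
* Median-of-ratios uses `exp(median(log ratio))`; ties and even gene counts
  therefore interpolate on the log scale.
* Clustering leaf order is deterministic (input-order tie-breaking as in
  agglomerative implementations); duplicated samples merge first at height
  exactly 0.
* The degenerate inputs each module rejects (zero-total samples,
  non-positive lengths, empty gene subsets, missing predecessor contrasts,
  lineage tags absent) raise errors naming the offending sample, gene or
  transition.

## Problem sizes used by the tests

The test and acceptance suites run the simulator at 200–5000 genes and the
built-in designs (25–39 samples), with 5–20 seeded replications for
calibration checks: null type-I error is assessed on 20 × 2000 genes at 3+3
replicates with planted α = 0.2, and EGA recovery on one 5000-gene
`design27` simulation. These sizes were chosen so each property is measured
with comfortable statistical margin while the whole suite stays quick to
iterate on.

## Limitations

The unreplicated mode inherits the anticonservativeness of all
single-library RNA-seq tests under biological overdispersion. The
method-of-moments dispersion is a floor, not a shrinkage estimator; with
more replicates a fitted trend would dominate it. FPKM is compositional:
between-stage comparisons of absolute FPKM conflate expression changes with
transcriptome-size changes, which is precisely why the staging rules are
threshold- and contrast-based rather than magnitude-based.
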