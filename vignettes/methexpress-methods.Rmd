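---
title: "Methods: differential methylome and transcriptome analysis with methexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylome and transcriptome analysis with methexpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpress)
```

# Scope and model

methexpress analyzes a two-condition (test vs control, e.g. spaceflight
vs ground), replicated, single-organ design with two data types: WGBS
per-cytosine counts and a gene-level RNA-seq count matrix. Organs are
analyzed independently throughout; a two-organ study is two runs of the
pipeline whose DEG sets are then compared (`deg_venn()`).

## Cytosine contexts

Plant methylation is context-specific: CG, CHG, CHH with H ∈ {A, C, T}.
Contexts are read 5'→3' on the cytosine's own strand, so a
reverse-strand cytosine (a G on the forward sequence at position p)
takes its downstream bases from the complements of positions p−1, p−2.
Coordinates are 0-based half-open internally; exported files use their
format's convention (BED/bedGraph 0-based half-open, site TSVs 1-based).

Degenerate inputs: a CG call needs only the next base, so it is made
even when the second downstream base is N or missing; CHG/CHH need both
downstream bases, and a site whose decisive bases are missing or N is
`UNKNOWN` and excluded from every downstream statistic. Exclusion is
conservative and keeps the denominator of every level well-defined. CG
sites stay strand-resolved: symmetric CG pairs are never merged, since
all site-level counting here is per cytosine.

## Methylation levels and the coverage gate

The level of a site is methylated/total reads; zero-coverage sites are
undefined (`NA`), never 0. A site enters the differential analysis only
with ≥ 10 reads in ≥ 2 replicates of *each* condition
(`coverage_gate()`, thresholds exposed). Condition-level summaries pool
counts across replicates (Σm/Σt) rather than averaging per-replicate
levels: pooling weights replicates by their information content and is
stable at low depth; with the near-equal sequencing depths of a
designed experiment the two estimators differ negligibly.

Ten-bin level distributions use half-open bins [0, 0.1) … [0.8, 0.9)
with a closed final bin [0.9, 1.0], so every defined level maps to
exactly one bin. Chromosome tracks tile fixed windows from position 0
(default 50 kb — chromosome-scale smoothness needs ≥ 10 kb windows);
windows without gated sites are omitted rather than reported as 0.

## Conversion efficiency

The chloroplast genome is unmethylated, so chloroplast methylated calls
measure bisulfite conversion failure. Efficiency is 1 − Σm/Σt pooled
over all chloroplast cytosines of a sample (all contexts), also
reported per context. With ~5,000 cytosines at 100× the binomial
standard error of the estimate is ≈ 2×10⁻⁴, far inside the ±0.2
percentage-point band the test suite checks.

## Site-level differential methylation

Replicates are pooled within condition and each gated site is tested by
a two-sided Fisher exact test on [[m_t, u_t], [m_c, u_c]]
(minimum-likelihood two-sided rule, identical to `stats::fisher.test`,
implemented as a vectorized hypergeometric sum and verified against an
exhaustive enumeration oracle to 10⁻¹²). Pooling is a deliberate model
choice: with 2–3 replicates per condition a between-replicate variance
component is barely estimable, and the pooled exact test is
deterministic and exactly testable. Its cost is that biological
replicate variability is not modelled, so p-values are calibrated under
exchangeable replicates — the empirical-FDR test in the suite shows the
BH-adjusted calls hold FDR ≤ 0.01 in that regime. Benjamini–Hochberg
runs once per organ across all contexts jointly, mirroring a single
site universe per organ; `diff` > 0 is hyper (higher in the test
condition).

## DMR calling

Windows are fixed, non-overlapping 100 bp tiles anchored at 0 — the
joining rule ("separated by not more than one window") presupposes a
fixed tiling. A window qualifies when it has ≥ 4 DmCs, an absolute
pooled level difference ≥ 0.2, and a BH-adjusted (per organ/context,
across all windows) Fisher test on window-pooled counts below 0.01 —
the same test one scale up, since the window-level significance is not
otherwise specified by the thresholds themselves. The min-diff
comparison carries a 10⁻⁹ tolerance so an exact-boundary difference
(e.g. pooled levels 0.7 vs 0.5) is not lost to floating-point
representation.

Qualifying windows of the same direction with a gap of ≤ 1 window are
joined; opposite-direction windows never join (a DMR has a direction).
Merged records re-aggregate `n_dmcs` and `mean_diff` over the member
windows only, not over the intervening gap window: the gap window
failed the gates, and aggregating members only preserves the defining
invariants (≥ 4 DmCs per merged record via its members, |mean diff|
≥ 0.2 up to coverage-weighting) by construction. The reported interval
still spans the gap.

## Gene annotation and metagene profiles

Genes are stored normalized (start < end plus strand); the TSS is the
5' body end on the gene's strand. Features (DmC positions, DMR
intervals) are assigned to the gene body, 2 kb upstream of the TSS, or
2 kb downstream of the TTS, strand-aware, flanks truncated at
chromosome ends. A feature hitting several (overlapping or adjacent)
genes is assigned to all of them — dropping or arbitrary tie-breaking
would lose information — and each (feature, gene) pair is classified
independently. "Genes affected" counts de-duplicate genes per
(region × context × direction) cell.

Metagene profiles rescale each gene body to 100 bins and cut each 2 kb
flank into 20 fixed 100 bp bins (defaults; both exposed). Genes whose
body is shorter than the body bin count are excluded rather than
upsampled, so no site is double-counted. Site levels are pooled across
genes per bin; minus-strand genes contribute mirrored, so profiles read
5'→3'. A mirror-symmetry property test (reverse-complementing the
genome and flipping gene strands leaves profiles unchanged) pins the
orientation conventions.

## Differential expression

CPM = count/library × 10⁶ and FPKM = CPM × 10³/length. The
low-expression gate keeps genes with CPM strictly above 5 in ≥ 3
libraries. Library scaling uses TMM factors (via edgeR's
`calcNormFactors`, the reference implementation of that normalization);
everything downstream is implemented in the package.

The test is a per-gene negative-binomial likelihood-ratio test: log
link, effective-library offsets, one mean (null) vs one mean per
condition (alternative), fitted by a vectorized Newton iteration;
p-values from χ²₁. Dispersions are estimated by Cox–Reid adjusted
profile likelihood on a 30-point log-spaced grid (10⁻⁴–4) and shrunk by
adding `prior_df/residual_df` (default 10/4) times the genewise-average
profile — the adjusted-profile-likelihood/empirical-Bayes scheme that
is standard for small-replicate RNA-seq. Method-of-moments estimators
were rejected: at n = 3 they are biased low and visibly inflate the
LRT tail. The remaining small-sample liberality of the χ² LRT at 3v3 is
modest; the suite's 20-seed 90%-null simulation holds the empirical DEG
FDR within Monte-Carlo error of the nominal 0.05.

A DEG satisfies q < 0.05 (BH within the organ), fold-change ≥ 2
(boundary included; |log2FC| ≥ 1 on fitted means), and mean FPKM > 0 in
at least one condition group. The FPKM clause is nearly vacuous as a
filter and is kept for interface fidelity; the CPM gate does the real
work.

## Integration

For each DEG with ≥ 1 mapped DmC, DmC-level differences are averaged
per (region × context) cell — DmC diffs, not region-wide level
differences, because the differential sites are the signal of
interest. The gene's trend requires sign unanimity across all
non-empty cells: *opposite* (methylation against expression),
*consistent* (with), otherwise *mixed*; exact-zero cell means carry no
sign, and a gene with only zero cells is unclassifiable. The three
labels partition the DmC-DEG genes, which is why opposite + consistent
counts can fall short of the total. Correlation summaries (Pearson with
a two-sided test, plus Spearman) need ≥ 3 genes per cell; smaller cells
are `NA`. Reference gene sets (ROS-signaling, housekeeping, …) are
plain one-column TSV inputs — external catalogs are data, not code.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all randomness flows from
its single seed (sub-streams per stage), and identical configs give
bit-identical data.

* **Design**: 2 conditions × 3 replicates of one organ. A two-organ
  study is two generated datasets — organs are analyzed independently,
  so nothing is gained by coupling them in one object.
* **Genome**: uniform-random nuclear chromosomes (default 2 × 250 kb)
  plus a 20 kb chloroplast; 100 non-overlapping genes (~40% gene
  density, Arabidopsis-like). These sizes keep a full pipeline run near
  10 s while leaving ~10⁵ cytosine sites per strand.
* **Baselines**: CG is a bimodal mixture of a high (Beta(20, 3),
  mean ≈ 0.87) and a near-zero (Beta(0.5, 30)) component with the
  mixing weight set to hit the configured mean 0.24 — real CG levels
  are U-shaped; CHG and CHH are unimodal Beta with means 0.10 and 0.05.
  These are conventional Arabidopsis values, not fitted to any dataset.
* **Counts**: per site/sample, total ~ Poisson(depth, default 30×) and
  methylated ~ Binomial(total, level). The chloroplast is fully
  unmethylated; its effective level is 1 − conversion efficiency
  (default 0.99). Nuclear conversion failure is not modelled — it
  would bias nuclear levels by ≤ 1% and is irrelevant to the contrasts.
* **Planted signal**: single-site DmCs shift by ±`dmc_effect` in a
  feasible direction; DMR intervals shift every informative site
  coherently. A hypo region only exists where there is methylation to
  lose, so hypo regions re-draw their ground state methylated
  (effect + headroom × Beta(2, 4)) before subtracting — subtracting
  from a near-zero baseline would clamp to ~0 difference and make the
  planted truth a fiction. Hyper regions re-base only the individually
  infeasible (already ~1) sites.
* **Expression**: log-normal baseline means, NB counts (Poisson at
  dispersion 0), per-sample library factors U(0.7, 1.3), planted DEGs
  at ±`deg_log2fc`. A configurable fraction of planted DEGs is
  *coupled*: their gene-body CG levels shift opposite in sign to the
  expression change, producing the negative body/CG
  methylation–expression correlation the integration stage should
  recover.

What the generator does *not* emulate — and what passing tests
therefore do not certify on real data: sequencing/mapping bias and
error, non-uniform coverage, biological replicate heterogeneity
(counts are exchangeable across replicates), linkage between
neighboring cytosines outside planted regions, TE/repeat structure,
and realistic gene-length/GC effects on expression.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical properties are sharp: 50,000
sites × 20 seeds for methylation FDR, 3,000 genes × 20 seeds for
expression FDR, 30 planted 300 bp DMRs at 100× for interval recovery,
~5,000 chloroplast cytosines at 100× for conversion recovery. Newton
fits clamp steps at ±3 and flag non-convergence (p set to 1); Fisher
tie comparison uses a 1 + 10⁻⁷ relative guard exactly as
`fisher.test` does; BH is `stats::p.adjust`.

Two fixture-design points worth recording. First, an effect-size sweep
in which *every* gene is up-regulated makes TMM normalization
unidentifiable (the trimmed mean lands inside the fold distribution
and biases every estimate), so the DEG sweep plants 180 of 500 genes
in random directions over a null background. Second, constructed DMR
windows place exact pooled counts, so gate behavior is checked at the
definitional boundaries (exactly 3 vs 4 DmCs, exactly 0.20 difference,
one- vs two-window gaps) with no sampling noise.

# Limitations

* The pooled Fisher DmC test does not model replicate variance; with
  heterogeneous replicates it will be anti-conservative. A
  beta-binomial layer is the natural extension and is deliberately out
  of scope.
* The NB LRT at 3v3 is slightly liberal in the extreme tail (χ²
  approximation); the DEG thresholds (FDR + fold + expression gates)
  absorb this in practice.
* DMR boundaries are window-quantized; true region edges inside a
  window are not refined.
* The FPKM > 0 DEG clause filters essentially nothing; it exists for
  interface fidelity with the stated thresholds.

```{r demo, eval = FALSE}
demo <- run_demo(seed = 1)
demo$recovery
```
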