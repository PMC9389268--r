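---
title: "Methods: inheritance patterns and expression heterosis in trio RNA-seq"
author: "triohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inheritance patterns and expression heterosis in trio RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triohet)
```

## The problem

Heterosis (hybrid vigor) is the superiority of an F1 hybrid over its inbred
parents. One transcriptional route to it is non-additive gene expression:
instead of sitting at the mid-parent level, a hybrid's expression of a gene
may match one parent (expression-level dominance) or fall outside the
parental range entirely (over-dominance). `triohet` implements the standard
analysis for a *trio design* — a female parent (F), a male parent (M) and
their F1 hybrid (H), each profiled with replicated RNA-seq — from a
gene-level count matrix through to per-gene inheritance patterns, heterosis
indices and term enrichment.

## Data model

The central container is `TrioExperiment`, an S4 class extending
`SummarizedExperiment`: a `counts` assay of non-negative integers with
unique gene and sample ids, `colData` columns `role`
(female_parent / male_parent / hybrid) and `replicate`, and optional
`rowData$length_bp` gene lengths. The validity method enforces all of this
at construction, so downstream code never re-checks it. Readers
(`readCountMatrix`, `readDesign`, `readGeneLengths`, `readAnnotation`)
reject malformed input with classed conditions
(`triohet_error_*`) rather than coercing; counts must be complete — there
is no missing-value convention, because imputed counts are not counts.

## Normalization

Two complementary quantities are computed from the counts.

**FPKM.** `computeFPKM()` uses
$\mathrm{FPKM}_{gs} = 10^9 \, c_{gs} / (T_s \, \ell_g)$ with $\ell_g$ the
annotated gene length and $T_s$ the per-sample total. Totals default to
column sums of the count matrix — downstream of a count matrix no other
library-size measure exists — and can be overridden with externally
supplied mapped-fragment totals. No fragment-length correction is applied:
counts arrive pre-aggregated per gene. The defining identity
$\sum_g \mathrm{FPKM}_{gs}\,\ell_g/10^3 \cdot T_s/10^6 = \sum_g c_{gs}$
is exact and property-tested to $10^{-9}$ relative tolerance.

**Size factors.** `sizeFactorsMedianRatio()` computes classical
median-of-ratios factors over genes with nonzero counts in every sample,
rescaled to geometric mean 1. These drive the differential-expression
normalization. The estimator assumes most genes are not differentially
expressed; see *Limitations*.

**Presence filter.** A gene counts as "expressed" in a genotype when its
mean FPKM there exceeds `minFpkm` (default 0, i.e. any signal). The
default scope `all_genotypes` keeps genes detected in F, M and H
simultaneously — the natural universe for three-way inheritance
classification; `any_genotype` is available for presence/absence Venn
analyses.

## Differential expression

`deTest()` compares two genotype groups per gene on median-of-ratios
normalized counts. The default method `nb_wald` fits a per-gene negative
binomial with variance $\mu + d\mu^2$:

* dispersion $d$ by method of moments, pooling the within-group variance
  across the two groups and flooring at $10^{-8}$;
* Wald statistic on $\log(\bar{x}_B + 1) - \log(\bar{x}_A + 1)$ with the
  delta-method standard error
  $\sqrt{(1/(\bar{x}_A{+}1) + d)/n_A + (1/(\bar{x}_B{+}1) + d)/n_B}$;
* two-sided p-value from a **t distribution with $n_A + n_B - 2$ degrees
  of freedom**.

The t reference is a deliberate design choice. With a plug-in
method-of-moments dispersion at the replicate numbers trio experiments
actually have ($n = 3$), a normal reference is markedly anticonservative
(empirical size $\approx 0.11$ at nominal 0.05 in our null simulations);
the t reference brings the empirical size to $\approx 0.04$, inside the
$[0.03, 0.07]$ band the test suite enforces, while costing essentially no
power at $n = 5$ (100% for 4-fold effects at dispersion 0.05). The
alternative `welch_log` is a Welch t-test on $\log_2(\text{normalized
count} + 1)$; zero-variance genes get $p = 1$ by convention.

DEG calling (`callDEGs`) uses the conventional thresholds **raw
$p < 0.05$ and fold change $> 2$ or $< 0.5$** (fold change on normalized
means with pseudocount 1). BH-adjusted q-values are always computed and
reported; `useQ = TRUE` switches the call to them. Genes with zero counts
across both groups are reported as `untested`, never silently dropped.

## The twelve inheritance patterns

Each gene in the classification universe (by default the union of DEGs
over the three contrasts H_vs_F, H_vs_M, F_vs_M) gets a
significant-direction trio $(s_{HF}, s_{HM}, s_{FM})$, each sign being
plus / zero / minus from the up / ns / down call of the corresponding
contrast. `classifyPattern()` then applies a fixed total mapping:

| pattern | trio (HF, HM, FM) | meaning |
|---|---|---|
| P1 | (−, +, +) | F > H > M, additive |
| P2 | (+, −, −) | M > H > F, additive |
| P3 | (+, 0, −) | H ≈ M, F < M, paternal dominant |
| P4 | (−, 0, +) | H ≈ M, F > M, paternal dominant |
| P5 | (0, −, −) | H ≈ F, F < M, maternal dominant |
| P6 | (0, +, +) | H ≈ F, F > M, maternal dominant |
| P7–P9 | (−, −, ·) | H below both parents (FM = +, 0, −) |
| P10–P12 | (+, +, ·) | H above both parents (FM = +, 0, −) |
| conserved | (0, 0, 0) | no significant differences |
| ambiguous | the other 14 trios | inconsistent at the thresholds |

Five-way categories group P1–P2 (additive), P3–P4 (paternal dominant),
P5–P6 (maternal dominant), P7–P9 (below low parent), P10–P12 (above high
parent); the three-way trichotomy groups additive / dominant (P3–P6) /
over-dominant (P7–P12). Within each dominant pair the lower index is the
case where the matched parent is the higher-expressed one — a labelling
convention only: every aggregate the package reports is invariant to
renumbering within a category. Classification is by significance calls,
not raw means, so a gene numerically between its parents but not
significantly different from either is *conserved*, not additive; this
makes the procedure reproducible and threshold-explicit. Exhaustive
enumeration of all $3^3 = 27$ trios (13 mapped + 14 ambiguous) and the
parent-swap symmetry (P1↔P2, P3↔P6, P4↔P5, P7↔P9, P10↔P12, P8 and P11
fixed) are pinned by tests.

## Heterosis statistics

For a trait with hybrid value $F_1$ and parent values giving high-parent
HP, mid-parent MP $= (P_f + P_m)/2$ and low-parent LP:
$\mathrm{OPH} = (F_1-\mathrm{HP})/\mathrm{HP} \times 100$,
$\mathrm{MPH} = (F_1-\mathrm{MP})/\mathrm{MP} \times 100$,
$\mathrm{BPH} = (F_1-\mathrm{LP})/\mathrm{LP} \times 100$; for positive
values with distinct parents OPH < MPH < BPH always. Per-gene
*expression heterosis* uses genotype mean FPKM: fold change
$\mathrm{FC} = F_1/\mathrm{MP}$ and heterosis percent
$H = (\mathrm{FC}-1) \times 100$ (computed in exactly that form so the
identity holds to the last bit). `formatHeterosisTable()` rounds to the
conventional 2-decimal presentation. The bundled
`kHeterosisGenes()` table of 28 potassium-transport- and
root-development-related genes from a tobacco G70 × GDH11 trio serves as
the worked example: recomputing FC from its printed F1 and MP columns
reproduces the printed FC exactly on the six rows with the largest
(most precisely printed) MP, and the printed heterosis percent to within
±1 point on all rows with MP ≥ 1 — the residual is pure input rounding,
since the printed columns carry only two decimals. Companion utilities
cover the flame-photometry potassium formula
($K^+\% = CV/(G \cdot 10^6) \times 100$) and qPCR relative expression by
$2^{-\Delta\Delta C_t}$.

## Enrichment

`enrichTerms()` performs hypergeometric over-representation of flat term
gene sets (GMT or two-column TSV) in a study list against a background.
The default background in the pipeline is the expressed-gene set (union
with the classified genes); the term universe is intersected with the
background and terms smaller than `minTermSize = 2` are dropped. p-values
are the exact upper tail $P(X \ge k)$ via `phyper`, q-values BH across
reported terms, rows ordered by p then term id so output is
deterministic. No ontology structure (parent propagation) is modelled —
terms are whatever flat sets the user supplies, which keeps results
independent of any ontology release.

## The simulator

`simulateTrio()` generates ground-truth trios: per gene a planted pattern
(exact counts by largest remainder over `patternFractions`), a log-normal
baseline mean, and genotype means separated by `effectSize` log2 units
according to the pattern's ordering — e.g. P11 plants equal parents with
the hybrid one effect size above, P1 plants F one step above H one step
above M. Counts are NB with variance $\mu + d\mu^2$ (this
parameterization is stated because "dispersion" is overloaded), means
scaled by per-sample log-uniform library factors; gene lengths are
log-uniform. Identical config + seed reproduce bitwise-identical output.

Defaults are the study conditions: 3 replicates per genotype, dispersion
0.05, effect size 2 (log2), 500 genes, and pattern fractions planting 40%
conserved genes with the pattern-bearing remainder split 10% additive /
30% dominant / 60% over-dominant, spread evenly over each category's
sub-patterns. Two of these choices deserve comment. First, the conserved
fraction exists because median-of-ratios normalization *assumes* most
genes are unchanged; a generator that makes every gene differential in
the same direction (e.g. all of the over-dominant mass on P10) lets the
hybrid's size factor absorb the planted effect and no method downstream
can recover it. Second, spreading each category over its sub-patterns in
both directions is what real trios look like — hybrids are not above
their parents for every single DEG. What the simulator does *not*
emulate: mean-dependent dispersion trends, correlated genes, batch
effects, and compositional (mRNA-amount) differences between genotypes —
so recovery tests demonstrate correctness of the machinery under the
stated model, not robustness to those real-data features.

`simulatePhenotype()` plants genotype means with log-normal replicate
noise at a given CV (exact at CV = 0), for validating the heterosis
indices; `defaultFixture()` writes a pinned 500-gene × 9-sample dataset
(seed 101) plus an annotation whose one planted term is drawn from
above-high-parent genes, used throughout the test suite and the README.

## Pipeline and determinism

`runPipeline()` chains read → normalize → filter → three DE contrasts →
Venn → pattern classification → expression heterosis → per-category
enrichment → report, configured by one YAML (or list) with every module
tunable exposed. All outputs are plain TSV/JSON, contain no timestamps,
and are byte-identical across reruns; the run summary echoes the full
configuration (minus the output path) and the package version. Logging
goes to stderr only. Problem sizes used by the validation suite — 500
genes × 5 replicates × 10 seeds for recovery, 20,000 gene-tests for null
calibration — were chosen as the smallest sizes at which the Monte-Carlo
noise is well below the tolerances being checked.

## Limitations

* The NB test is a deliberately simple per-gene estimator: no dispersion
  shrinkage across genes, no fold-change moderation. On real data its DEG
  lists will differ from shrinkage-based tools, particularly for weakly
  expressed genes; the package's claims are calibration and planted-truth
  recovery, not equality with any specific external tool.
* Classification inherits the thresholds' arbitrariness: a gene just
  missing significance against one parent slides between a dominant
  pattern and conserved/ambiguous. Report proportions, not individual
  gene labels, when effects are marginal.
* Ratio-based heterosis indices require nonzero parent values and explode
  as MP → 0; the per-gene table therefore excludes genes with zero
  mid-parent expression.
* Enrichment results are only as good as the supplied annotation; no
  identifier mapping is performed.
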