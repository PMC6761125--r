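---
title: "Methods: 3' Pol II pausing, TES shifts, and transcriptional interference at tandem genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3' Pol II pausing, TES shifts, and transcriptional interference at tandem genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausepoint)
```

## The problem

RNA polymerase II frequently accumulates just downstream of the transcript
end site (TES) — 3′ pausing. At *tandem* gene pairs (two genes on the same
strand, the upstream gene's 3′ end facing the downstream gene's promoter),
this pause zone acts as a buffer: when it weakens or moves downstream, the
upstream gene's polymerase encroaches on the downstream promoter and can
repress it — transcriptional interference (TI). `pausepoint` provides the
quantitative machinery to measure 3′ pausing, compare it between genotypes,
localize its displacement, characterize the genomic contexts in which
interference occurs, and detect interference being switched on or off when
the upstream gene's expression is re-leveled (for example by light during
photomorphogenesis).

All user-facing functions take plain tibbles (gene models, neighbor contexts,
differential-expression tables) and return tibbles; dense per-bp signal
travels in a light `coverage_track` container indexed by chromosome.

## Coordinates and gene models

Internally every interval is **0-based, half-open** `[start, end)`, matching
BED and simplifying interval arithmetic; GFF3's 1-based closed coordinates
are converted on read (`load_annotation()`) and write (`write_gff3()`). The
TSS is `start` for a plus-strand gene and `end - 1` for a minus-strand gene;
the TES is the opposite boundary. Multi-isoform structure is out of scope: a
gene is its annotated span, with optional UTR/exon sub-features carried in a
`features` attribute. Genes with no explicit exons are treated as one exon
spanning the gene (otherwise the "gene body minus exons" intron rule would
label the whole body intronic).

## Neighbor contexts

For each gene, `neighbor_contexts()` finds the nearest gene on each side of
the genome axis (genes fully nested inside another gene are skipped as
candidates), relabels the sides upstream/downstream relative to the focal
strand, and classifies pairs as tandem (same strand), divergent
(head-to-head) or convergent (tail-to-tail). The intergenic distance is the
gap between gene bodies; for a tandem pair this equals the distance from the
upstream TES to the downstream TSS. Overlapping pairs are reported with
distance 0 and an `overlap` flag and are excluded from distance
distributions. A separate `tss_to_border` distance (focal TSS to the nearest
border of the upstream gene, regardless of that gene's strand) supports the
distance binning of light-induced genes. On sorted non-overlapping
chromosomes a vectorized scan is used; it is verified in the tests to agree
with the general scan.

## Peak annotation

Peak summits are assigned to exactly one category in fixed precedence:
promoter, immediate downstream, 5′UTR, 3′UTR, exon, intron, intergenic. The
promoter and immediate-downstream windows are strand-aware and cover
distances 1–300 bp from the TSS/TES respectively; "intergenic" means more
than 300 bp from any gene. (Read literally, "<300 bp" flank windows and a
">300 bp" intergenic rule leave a summit at exactly 300 bp unassigned; we
close that boundary by including distance 300 in the flank windows.) Ties
among genes within the winning category are broken by summit-to-anchor
distance (TSS for promoter/5′UTR, TES for downstream/3′UTR, the nearer of
the two for exon/intron), then lexicographic gene id — arbitrary but
reproducible. Enrichment per category is assessed against `n_samples`
replicate sets of uniform random non-blacklisted positions, with add-one
empirical p-values; two-sided p-values are reported alongside the one-sided
tails.

## Coverage, normalization and the pausing index

Fragment BED input is converted to per-bp overlap counts (with an optional
70–250 bp fragment-length filter for nucleosomal data); bedGraph input is
expanded to per-bp values with overlapping intervals rejected. FP10M
normalization multiplies raw counts by `1e7 / total fragments`; it is linear,
so every density *ratio* downstream is invariant to it.

The **3′ pausing index** of a gene longer than 1 kb is

> PI = mean coverage over (TES, TES + w] / mean coverage over [TSS, TES)

computed in the direction of transcription. The TES window width `w`
defaults to 200 bp: the definition is pictorial in the source material, and
every property we assert (oracle equivalence, scale invariance, detection of
an amplitude change) holds for any fixed window; 200 bp covers the pause
zone (bump center ~100 bp, sd ~50 bp) without reaching the next gene in most
pairs. Optional body trims from either end default to 0. Genes whose index
is undefined (zero body or zero window density) are flagged and excluded
from tests rather than pseudocounted, since log2 indexes presuppose positive
densities. TES windows that intrude into a neighboring gene body are flagged
(`tes_in_gene`) but retained — intrusion is the phenomenon under study.

`compare_pausing()` pairs records by gene, tests the difference in mean log2
PI per expression group with a paired Student's t test, and BH-adjusts across
all (group × antibody) tests of the run. Identical inputs return the p = 1
convention; groups with fewer than 3 complete pairs are NA.

## Metagene profiles and winsorization

Anchored profiles extract strand-aware per-gene windows (minus-strand windows
reversed so offsets always increase with transcription), pool all window
values, replace the most extreme `winsor_pct`% (default 0.01%, i.e. capping
at the 99.99th percentile) by the cap value — one-sided, upper only — and
average per offset. The winsorization pool is the window set of the current
gene selection, so the cap adapts to each plot's dynamic range; a single
extreme locus cannot dominate the mean. The confidence band is the normal
approximation `mean ± z·sd/√n` with `z = 1.959964` at the default 95% level;
no bootstrap is implemented because the normal approximation is adequate at
the gene counts involved (hundreds), and the CI-vs-√n scaling is verified in
the tests. Windows truncated at chromosome ends contribute only to the
offsets they cover (per-offset `n` bookkeeping) rather than being dropped.

Gene-body profiles first average each gene's body into 100 equal-fraction
bins (bp `j` of an `L`-bp body belongs to bin `⌊j·100/L⌋ + 1`, so genes whose
signal is constant within each 1%-of-length segment produce identical bin
vectors regardless of length); flanks are kept at 1 bp resolution for
profiles or 20 bp for heatmap grids. `profile_argmax()` returns the offset of
the maximum mean in a search window, breaking ties toward the anchor and then
toward the lower offset, and warns on flat windows.

## TES shifts

The population-level shift between two conditions is the difference of the
TES-anchored average-profile argmax positions over the same gene set, inside
a ±1000 bp search window (matching the plotted extent of the underlying
experiments). Per-gene shifts use the raw, unwinsorized window coverage with
the same tie rules; genes whose window maximum does not exceed `min_signal`
(default 0) in both tracks are dropped, never zero-imputed. Because per-gene
argmax positions on integer count data are tie-broken toward the anchor, the
per-gene median shift is mildly conservative (a few bp below the planted
displacement at realistic noise); the population estimator is unbiased, with
a per-seed standard deviation of ~4 bp at 500 genes, so planted shifts of
0–150 bp are recovered to within ±2 bp on average across seeds. Group shifts
are tested against the all-expressed-genes mean shift with a one-sided
Wilcoxon signed-rank test, BH-adjusted across groups.

## Greylist and nucleosome-free regions

`build_blacklist()` flags genome bins (default 1 kb, unstated in the source
material) with systematically high control signal: per control, a negative
binomial is fitted by the method of moments to each of `n_random` random
samples of `sample_size` bins (Poisson fallback when variance ≤ mean); the
bin threshold is the median of the fitted 95th-percentile counts; bins
exceeding their threshold in more than half the controls are flagged and
adjacent flagged bins merged. The same random bin samples are used for every
control, making the output invariant to control ordering under a fixed seed.
Manual genome-browser refinement of the regions is inherently irreproducible
and is not modeled.

`call_nfr()` returns maximal runs of more than 500 bp where both the MNase
and H3 tracks are below their genome-wide first quartiles (computed over all
bases, zeros included), minus any excluded regions. The run-length threshold
is strict, and the conjunction of both tracks is required.

## TI selection procedures

`select_ti_up()` and `select_ti_relief()` implement the threshold-based
selection of tandem pairs closer than 600 bp, with every inequality strict
and in the stated direction: fold-changes are linear ("fold-change > 2" means
log2FC > 1 in the stated direction), "not differentially expressed" requires
both the fold-change and the adjusted-p condition, the pre-existing-TI filter
uses the *raw* dark p-value (< 0.05 with negative log2FC), and the
upregulated arm requires all four light contrasts (both genotypes × both time
points) whereas the downregulated relief arm requires both genotypes at 2 *or*
at 4 h, following the differing wording of the two designs. Boundary cases
(fold-change exactly 2, p exactly 0.05, distance exactly 600) are excluded
and fixed in the test suite. The Wilcoxon tests of the dark-to-light change
in log2(mutant/wt) default to two-sided, with the sidedness exposed, since
the original description does not state it; the orientation × distance
analysis of light-induced genes uses Mann–Whitney tests of same- vs
opposite-strand genes per condition and distance bin (<600, 600–1200,
>1200 bp), BH-adjusted across all comparisons, with bins under 5 genes per
side reported NA. One BH family per analysis (per figure-panel equivalent)
is used throughout.

## Statistical kernels

The named tests are implemented in-package so that the exact code paths used
by the pipeline can be validated against enumeration oracles: Wilcoxon
signed-rank (exact by a rank-sum DP over all 2^n sign assignments for n ≤ 25,
midrank ties handled within the conditional distribution; normal
approximation with tie and continuity corrections above), Mann–Whitney U
(exact by arrangement enumeration for min(n, m) ≤ 8 without ties), two-sample
KS (asymptotic Kolmogorov series), Fisher exact on 2×2 tables (hypergeometric;
two-sided p sums probabilities ≤ the observed table's), paired t, and BH
step-up adjustment (monotone-enforced, capped at 1, NA-propagating). Base R's
`wilcox.test`, `ks.test`, `fisher.test`, `t.test` and `p.adjust` serve as
independent cross-checks in the test suite only. Degenerate inputs follow
fixed conventions: all-zero differences give p = 1 with a warning; a
zero-margin 2×2 table gives p = 1 with a warning.

## The synthetic-data generator

`gen_annotation()` lays `n_genes` head-to-tail on one chromosome. Gene
lengths are log-normal (median 2 kb, floor 1.1 kb so nearly all genes pass
the 1 kb pausing-index filter); background intergenic gaps are log-normal
with median 859 bp — the genome-wide tandem-pair median reported for the
biological system — and strands follow a two-state chain with
`fraction_tandem = 0.5` (independent strands, 50% tandem background). A
planted *protected* subset (default 15% of genes; enriched relative to the
real system's ~1.5% to give desk-scale statistical power) is placed on the
plus strand with a same-strand upstream neighbor with probability 0.74, at
short gaps (log-normal median 244 bp), and with the upstream neighbor's
expression boosted by +1.32 log2 (~2.5-fold) — the context structure reported
for protected genes. Because planted short pairs are 15% of the genome, the
*observed* all-tandem median gap sits below the 859 bp background law
(~700 bp); the per-set medians remain exactly recoverable from the
bookkeeping.

`gen_coverage()` builds the expected per-bp signal — a body plateau
proportional to linear expression (ramped 0.5→1.5 for the S2P-like profile),
a Gaussian 3′ bump centered 100 bp past the TES with sd 50 bp and amplitude
4× the plateau (near the reported TES maxima of ~106–131 bp downstream), and
a TSS bump for the S5P-like profile — then Poisson-samples it. In the mutant
the bump amplitude is multiplied by 0.5 and its center moved `shift_bp`
(default 96 bp, echoing the observed displacement) downstream for genes in
the configured scope; both are ordinary parameters, not claims about real
data. Control tracks are flat background with planted hot regions;
nucleosome-like tracks are flat.

`gen_de_tables()` simulates negative-binomial counts (3 replicates per
genotype × condition, size 100 ≈ dispersion 0.01, typical of well-replicated
RNA-seq at moderate-to-high expression; ~200 counts for a median gene) from
planted light responses and mutant/wt ratios, and derives per-contrast log2
fold-changes, Welch-t p-values on log2 counts, and BH adjustment — a
deliberately simple stand-in for a full count-model fit, sufficient for
threshold-procedure validation. Light-dependent TI is planted through two
routes, selectable via `light$ti_scope`: the downstream partner of a
light-induced upstream gene loses a further `ti_effect` log2 units of
mutant/wt ratio under light (the paired-design structure), and a
light-induced gene closer than 600 bp downstream of any same-strand neighbor
loses the same (the orientation × distance structure); protected genes with a
light-repressed upstream neighbor gain `relief_effect`. Loops are Bernoulli
with a doubled rate in the upstream-tandem-of-protected context.

All generator outputs are pure functions of (configuration, seed); every
planted quantity is recorded in the `truth` tibble.

## What the synthetic data does and does not emulate

It reproduces the *structure* the analyses rely on: strand-aware signal
shapes, expression-proportional coverage, Poisson sampling noise,
condition-paired effects, context-dependent pair geometry, artifact hot
regions, and DE-table anatomy. It does not emulate mappability, GC or
fragment-size biases, isoform structure, replicate-level ChIP variability,
or genuinely correlated neighboring-gene expression. Passing tests therefore
demonstrate that the estimators and selection procedures are correct and
well calibrated under controlled conditions — not that any biological claim
holds in new data.

## Problem sizes and numerical choices

The validation suite runs at desk scale: 100–600 genes for most checks, 500
genes × 50 seeds for shift recovery, 200 genes × 50 seeds for
detection/type-I rates, and 2000 genes (approximating the real system's
~400-gene protected set) for context statistics and loop enrichment.
Winsorization uses type-7 quantiles; the shift search window is ±1000 bp;
ties everywhere break toward the anchor then the lower coordinate; BH
families are per analysis run. Known limitations: per-gene argmax shifts are
a few bp conservative on integer counts (tie rule); the empirical
position-enrichment test needs `n_samples` large for small p-values (add-one
correction floors p at `1/(n_samples+1)`); and the greylist's
method-of-moments NB fit can be anti-conservative for heavy-tailed controls,
where the majority rule across controls provides the protection.
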